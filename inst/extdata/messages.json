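{
  "en": {
    "LEAN_FORWARD": "please lean forward",
    "LEAN_BACKWARD": "please lean backward",
    "LEAN_RIGHT": "please lean to the right",
    "LEAN_LEFT": "please lean to the left",
    "CONGRATULATION_1": "great, you are back in your best posture",
    "CONGRATULATION_2": "well done, posture recovered",
    "CONGRATULATION_3": "excellent, that is your best posture again",
    "PRAISE_MAINTAINED": "very good, keep maintaining your posture",
    "CALIBRATION_DONE": "calibration complete, this is now your best posture"
  },
  "es": {
    "LEAN_FORWARD": "por favor, inclínese hacia adelante",
    "LEAN_BACKWARD": "por favor, inclínese hacia atrás",
    "LEAN_RIGHT": "por favor, inclínese hacia la derecha",
    "LEAN_LEFT": "por favor, inclínese hacia la izquierda",
    "CONGRATULATION_1": "genial, ha vuelto a su mejor postura",
    "CONGRATULATION_2": "muy bien, postura recuperada",
    "CONGRATULATION_3": "excelente, esa es de nuevo su mejor postura",
    "PRAISE_MAINTAINED": "muy bien, siga manteniendo su postura",
    "CALIBRATION_DONE": "calibración completa, esta es ahora su mejor postura"
  },
  "pt": {
    "LEAN_FORWARD": "por favor, incline-se para a frente",
    "LEAN_BACKWARD": "por favor, incline-se para trás",
    "LEAN_RIGHT": "por favor, incline-se para a direita",
    "LEAN_LEFT": "por favor, incline-se para a esquerda",
    "CONGRATULATION_1": "ótimo, você voltou à sua melhor postura",
    "CONGRATULATION_2": "muito bem, postura recuperada",
    "CONGRATULATION_3": "excelente, essa é novamente a sua melhor postura",
    "PRAISE_MAINTAINED": "muito bem, continue mantendo a sua postura",
    "CALIBRATION_DONE": "calibração concluída, esta é agora a sua melhor postura"
  }
}
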