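# shared fixtures, all built in code

upright_ref <- function() {
  structure(list(r0 = c(0, 1, 0), created_at = "1970-01-01T00:00:00Z"),
            class = "calibration_reference")
}

gravity_row <- function(gx, gy, gz, t = 0) {
  data.frame(t = t, gx = gx, gy = gy, gz = gz, valid = TRUE)
}

# angle stream with constant deviation over integer seconds
angle_stream <- function(t, frontal = 0, lateral = 0) {
  data.frame(t = t, frontal_deg = rep_len(frontal, length(t)),
             lateral_deg = rep_len(lateral, length(t)))
}

# the hand-enumerated toy stage: IN [0,20), OUT [20,30), IN [30,100),
# OUT [100,105), IN [105,120], 1 Hz records
toy_log <- function() {
  t <- 0:120
  state <- rep("IN", length(t))
  state[t >= 20 & t < 30] <- "OUT"
  state[t >= 100 & t < 105] <- "OUT"
  session_log(
    subject_id = "toy", stage_label = "feedback_on",
    config = posture_config(), calibration = upright_ref(),
    angle_records = data.frame(t = t, frontal_deg = 0, lateral_deg = 0,
                               posture = state),
    events = list())
}

# small, fast scenario for bulk log generation
quick_scenario <- function(seed = 1L, duration_s = 60) {
  session_scenario(duration_s = duration_s, sample_rate_hz = 25,
                   engine_rate_hz = 5, deviation_rate_per_min = 3,
                   rng_seed = seed)
}

event_kinds <- function(log) vapply(log$events, `[[`, "", "kind")
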