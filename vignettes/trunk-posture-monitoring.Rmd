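---
title: "Trunk posture monitoring from a chest-worn accelerometer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trunk posture monitoring from a chest-worn accelerometer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunksense)
```

## The problem

People with post-stroke hemiparesis often lose awareness of their trunk
alignment: the weak side drifts into flexion or lateral lean, and the
patient notices only through pain, fatigue, or a therapist's prompt.
A chest-worn smartphone can close that loop. Its accelerometer senses
the direction of gravity in the device frame; once a therapist
calibrates the patient's *best-at-the-time posture* — the most aligned
posture the patient can achieve at that moment, not an able-bodied
ideal — any subsequent tilt of the trunk shows up as a rotation of the
gravity vector away from the calibrated direction. `trunksense`
implements that monitoring engine headlessly: angle estimation,
a multisensory feedback state machine, session logging, per-stage
analytics, and a trunk-movement simulator that stands in for both the
wearer and an optical motion-capture reference rig.

## Angle model

Device convention: the phone sits in portrait on the sternum, screen
outward; $+y$ points toward the head, $+x$ toward the wearer's right,
$+z$ out of the chest. An upright wearer at rest reads specific force
$\approx (0, +g_0, 0)$ with $g_0 = 9.80665\,\mathrm{m/s^2}$.

Let $\hat g$ be the unit gravity direction and $\hat r_0$ the
calibrated reference. The engine uses *per-plane projected angles*:

$$
\theta_{front} = \operatorname{atan2}(\hat g_z, \hat g_y) -
                 \operatorname{atan2}(r_{0z}, r_{0y}), \qquad
\theta_{lat} = \operatorname{atan2}(\hat g_x, \hat g_y) -
               \operatorname{atan2}(r_{0x}, r_{0y}),
$$

each wrapped to $(-180, 180]$ degrees. Positive frontal means leaning
forward, positive lateral means leaning toward the wearer's right.
This decomposition was chosen over a single total-tilt angle or an
Euler-angle factorization because the feedback rules apply *independent*
per-plane thresholds: each plane's angle must depend only on the
gravity components in that plane. A consequence worth stating plainly:
for compound tilts the pair $(\theta_{front}, \theta_{lat})$ is a
chart on the sphere of gravity directions, not a pair of sequential
Euler angles — composing a 10° pitch *then* a 60° roll as rotation
matrices yields a projected frontal angle near 19°, which is a property
of Euler composition, not an estimator error. The simulator therefore
parametrizes compound ground truth directly in this chart: a target
$(f, l)$ is realized as the minimal (Rodrigues axis–angle) rotation
taking $(0,1,0)$ to $\operatorname{normalize}(\tan l,\, 1,\, \tan f)$,
optionally composed with a yaw about the world vertical. The
construction path (axis–angle algebra) is independent of the recovery
path (atan2 projections), so oracle tests are meaningful, and for
single-plane movements the construction reduces to a plain single-axis
rotation. Axial (yaw) trunk rotation leaves gravity fixed and is
*physically unobservable* from a static accelerometer; the package
asserts this invariance rather than pretending to score rotation.

Two caveats of the angle model, stated openly: it assumes quasi-static
movement (specific force ≈ gravity; fast movements add linear
acceleration that the magnitude gate only partially rejects), and it
cannot separate trunk tilt from the phone shifting inside the vest
pocket.

## Signal conditioning

Samples whose magnitude falls outside $[0.5\,g_0, 3\,g_0]$ (free fall,
impact, shaking) are flagged invalid; they never update the smoother
but carry the last estimate forward, so a brief knock does not produce
a spurious posture excursion. Smoothing is a per-axis exponential
moving average with $\alpha = 0.2$ per sample at 50 Hz (time constant
≈ 0.1 s), seeded with the first valid sample. An EMA was chosen
because it is causal, constant-memory and cheap enough for a low-end
phone; its cost is a small lag (≈ 0.08 s at the default settings),
visible as a transient error during fast ramps. Zero-noise kinematic
checks therefore run with $\alpha = 1$ (smoothing off) to isolate the
angle computation, while the noise-robustness check keeps the default
$\alpha$ and absorbs the lag into its error budget. Calibration takes
the normalized mean of the last second of valid estimates.

## Feedback state machine

The engine consumes the angle stream and a configuration:

| parameter | default | meaning |
|---|---|---|
| `frontal_threshold_deg`, `lateral_threshold_deg` | 5°, 5° | allowed deviation per plane |
| `tolerance_s` | 3 s | time beyond threshold before audio guidance |
| `hysteresis_deg` | 0° | re-entry margin below threshold |
| `directive_repeat_s` | = `tolerance_s` | repeat interval while still out |
| `praise_interval_s` | 300 s | praise after this much continuous in-posture time |
| `vibration_enabled`, `audio_enabled`, `visual_enabled` | on | feedback channels |
| `language` | `en` | `en`, `es`, `pt` |
| `rng_seed` | 1 | congratulation-variant draw |

Rules: crossing a threshold turns the screen red and fires one
vibration (on the transition only — continuous buzzing would habituate
quickly); if the patient stays out longer than the tolerance, a
directional instruction is spoken — the corrective *opposite* of the
dominant deviation, dominance judged by the deviation/threshold ratio
with ties going to the frontal plane — and repeats every
`directive_repeat_s`; returning to posture turns the screen green and
plays one of three congratulation variants chosen by a seeded Lehmer
generator (reproducibility over true randomness); every 5 continuous
in-posture minutes earns praise, with the clock reset on each return
(the stricter of the two readings of "every 5 minutes", and the one
that rewards *maintained* posture). Default hysteresis is 0 to match
the simple threshold rule; it exists because a patient hovering at the
boundary would otherwise chatter between states. Disabled channels
never emit. All engine decisions take time from the sample stream,
never the wall clock, so every pipeline is replayable.

Directive texts in English are the app's four spoken strings
("please lean forward", "please lean backward", "please lean to the
right", "please lean to the left"); Spanish and Portuguese texts are
translations authored for this package.

## Session logs and metrics

A stage's record is one JSON document in an OpenMHealth-style envelope
(header: schema id, subject, stage label, configuration and calibration
snapshots; body: 1 Hz angle records with posture classification, plus
every feedback and interaction event). One record per second mirrors
the original app's logging cadence. `read_session_log()` is the exact
inverse of `write_session_log()`, and validation failures name the
offending field. The schema ships in
`inst/extdata/session-log-schema.json`; validation itself is
implemented in R.

Per-stage metrics operationalize the study outcomes. A *maintained
position* is an in-posture episode lasting at least `min_hold_s`
(default 5 s — long enough to exclude mere pass-throughs, short enough
to credit genuine holds; the threshold is configurable and reported
with the output because "could maintain" has no canonical definition).
*Corrective movements* are completed out-to-in transitions; the count
of out-episodes is also emitted as an alternative. Two tests are
provided: a paired two-tailed $t$ on per-subject stage pairs (the
within-subjects analysis) and Welch's unequal-variance $t$ computed
from group summaries alone,

$$
t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},
$$

with Welch–Satterthwaite degrees of freedom — the only analysis that
can be checked from published means and SDs when raw data are
unavailable.

## The simulator as study stand-in

`simulate_stage()` emulates one monitored stage: the wearer starts
upright (the first second doubles as the calibration window), episodic
deviations arrive as a Poisson process (default 1.5/min), each a
random flexion/extension/bend with amplitude uniform on 10–25° and
cosine ramps of 0.5–1.5 s (smooth starts and ends; the movements begin
and end upright). How long a deviation lasts is the behavioral core:
with feedback on, the patient corrects after the tolerance plus a
log-normal latency (meanlog $\log 3$ s, sdlog 0.4) — prompt-triggered
correction; with feedback off, after a log-normal self-initiated
latency (meanlog $\log 15$ s, sdlog 0.5). Defaults: 9-minute stages
(matching the observed mean stage durations), 50 Hz sampling, 0.2
m/s² noise, engine evaluation at 10 Hz. A feedback-off stage runs the
*same* engine with all channels silenced rather than bypassing it, so
movements are classified and logged identically in both conditions.

What the simulator does *not* emulate: linear accelerations from
walking, vest-pocket slippage, sensor bias and axis misalignment,
fatigue drift within a stage, or any biomechanics of hemiparesis. Tests
that pass on simulated data therefore validate the *engine* — angle
recovery, event timing, logging, metric derivation, statistical
machinery — not clinical effectiveness on real patients.

Problem sizes used by the validation suite and the acceptance script:
1000 random orientations for the angle oracle, 100 short (45–90 s)
stages for the round-trip check, and 40 subjects × 2 stages (the
study's cohort size) for the within-subjects recovery, repeated over 5
seeds in the test suite.

## Numerical choices and degenerate inputs

- Angles wrap to $(-180, 180]$; the identity orientation gives exactly
  $(0, 0)$.
- `atan2` handles the poles; tilts are restricted below 90° in the
  simulator, where the tangent chart is well defined.
- A window with no valid estimate refuses to calibrate; an invalid
  gravity estimate refuses to produce angles (errors, not NaNs).
- Zero-variance statistical inputs: equal-mean zero-variance groups
  give $p = 1$ by convention; unequal-mean zero-variance inputs are
  rejected as degenerate rather than reported as $t = \infty$.
- Both groups in a summary test need $n \ge 2$; a paired test needs
  at least 2 pairs.
- The congratulation RNG is a 31-bit Lehmer generator whose products
  stay below $2^{53}$, so the sequence is exactly reproducible in
  double arithmetic on any platform.

## Known limitations

Axial rotation is unobservable by design (stated above). The tilt
chart distorts compound frontal+lateral tilts relative to sequential
Euler angles; within the ±5° thresholds the difference is negligible,
but reports of large compound deviations should be read as chart
coordinates, not as anatomical Euler angles. The EMA introduces lag
proportional to movement speed. The simulator's latency distributions
encode a *assumed* behavioral difference between conditions; the
within-subjects recovery test demonstrates that the pipeline detects
such a difference when present, not that real patients behave this way.
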