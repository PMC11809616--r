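MOVEMENT_KINDS <- c("FLEXION", "EXTENSION", "BEND_LEFT", "BEND_RIGHT",
                    "ROTATE_LEFT", "ROTATE_RIGHT", "HOLD")

#' A single trunk movement primitive
#'
#' One episodic trunk movement: the wearer starts upright, ramps to the
#' peak amplitude over `rise_s` (cosine ramp), holds it for `hold_s`,
#' and returns to upright over `return_s`. Flexion/extension tilt the
#' trunk forward/backward (frontal plane angle), the bends sideways
#' (lateral), and the axial rotations turn about the gravity axis
#' (invisible to the accelerometer's gravity vector, by physics).
#'
#' @param kind one of `r paste(MOVEMENT_KINDS, collapse = ", ")`.
#' @param amplitude_deg peak angle, non-negative degrees (< 90).
#' @param rise_s,hold_s,return_s phase durations, non-negative seconds.
#' @return object of class `movement_primitive`.
#' @export
movement_primitive <- function(kind, amplitude_deg = 0, rise_s = 1,
                               hold_s = 1, return_s = 1) {
  kind <- match.arg(kind, MOVEMENT_KINDS)
  stopifnot(amplitude_deg >= 0, amplitude_deg < 90,
            rise_s >= 0, hold_s >= 0, return_s >= 0)
  structure(list(kind = kind, amplitude_deg = amplitude_deg,
                 rise_s = rise_s, hold_s = hold_s, return_s = return_s),
            class = "movement_primitive")
}

# cosine ramp profile of one primitive evaluated at local times u
primitive_profile <- function(p, u) {
  a <- numeric(length(u))
  r1 <- p$rise_s; r2 <- p$rise_s + p$hold_s; r3 <- r2 + p$return_s
  up <- u >= 0 & u < r1
  if (any(up)) a[up] <- p$amplitude_deg * (1 - cos(pi * u[up] / r1)) / 2
  hold <- u >= r1 & u < r2
  a[hold] <- p$amplitude_deg
  down <- u >= r2 & u < r3
  if (any(down) && p$return_s > 0) {
    a[down] <- p$amplitude_deg * (1 + cos(pi * (u[down] - r2) / p$return_s)) / 2
  }
  a
}

#' Rotation matrix realizing target tilt and yaw angles
#'
#' Builds the device-to-world rotation whose device-frame gravity
#' direction projects to exactly the requested frontal and lateral
#' angles: the tilt part is the minimal (axis-angle) rotation taking
#' upright (0, 1, 0) to normalize((tan lateral, 1, tan frontal)),
#' composed with a yaw about the world vertical (yaw first in the
#' composition, so gravity is unaffected by it).
#'
#' @param frontal_deg,lateral_deg,yaw_deg target angles, degrees;
#'   tilts must be within (-90, 90).
#' @return 3x3 rotation matrix `R`; the simulated accelerometer reading
#'   is `t(R) %*% c(0, G0, 0)`.
#' @export
rotation_from_angles <- function(frontal_deg, lateral_deg, yaw_deg = 0) {
  stopifnot(abs(frontal_deg) < 90, abs(lateral_deg) < 90)
  d2r <- pi / 180
  v <- c(tan(lateral_deg * d2r), 1, tan(frontal_deg * d2r))
  v <- v / sqrt(sum(v^2))
  # Rodrigues: minimal rotation M taking u = (0,1,0) to v
  k <- c(v[3], 0, -v[1])          # u x v
  s <- sqrt(sum(k^2)); cc <- v[2]
  if (s < 1e-15) {
    M <- diag(3)
  } else {
    k <- k / s
    K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                3, 3, byrow = TRUE)
    M <- diag(3) + s * K + (1 - cc) * (K %*% K)
  }
  psi <- yaw_deg * d2r
  Ryaw <- matrix(c(cos(psi), 0, sin(psi), 0, 1, 0, -sin(psi), 0, cos(psi)),
                 3, 3, byrow = TRUE)
  Ryaw %*% t(M)
}

#' Orientation trajectory from a primitive sequence
#'
#' Concatenates movement primitives into a sampled trunk-orientation
#' trajectory with per-sample ground truth (frontal tilt, lateral tilt,
#' yaw) and the device-frame gravity direction each orientation
#' produces. Rotation matrices are included on request (the ground
#' truth for the rotation-matrix oracle).
#'
#' @param primitives list of [movement_primitive()]s, played in order.
#' @param rate sample rate, Hz.
#' @param include_rotations also build the 3x3xN rotation array
#'   (omitted by default; gravity directions suffice for synthesis).
#' @return object of class `trunk_trajectory`: list with `truth`
#'   (data.frame `t`, `frontal_deg`, `lateral_deg`, `yaw_deg`),
#'   `gravity` (N x 3 unit vectors, device frame) and optionally
#'   `rotations`.
#' @export
trajectory <- function(primitives, rate = 50, include_rotations = FALSE) {
  stopifnot(length(primitives) > 0)
  durs <- vapply(primitives, function(p) p$rise_s + p$hold_s + p$return_s,
                 numeric(1))
  total <- sum(durs)
  t <- seq(0, total, by = 1 / rate)
  starts <- cumsum(c(0, durs[-length(durs)]))
  frontal <- numeric(length(t)); lateral <- numeric(length(t))
  yaw <- numeric(length(t))
  for (i in seq_along(primitives)) {
    p <- primitives[[i]]
    in_p <- t >= starts[i] & (t < starts[i] + durs[i] | i == length(primitives))
    if (!any(in_p)) next
    a <- primitive_profile(p, t[in_p] - starts[i])
    switch(p$kind,
           FLEXION = frontal[in_p] <- frontal[in_p] + a,
           EXTENSION = frontal[in_p] <- frontal[in_p] - a,
           BEND_RIGHT = lateral[in_p] <- lateral[in_p] + a,
           BEND_LEFT = lateral[in_p] <- lateral[in_p] - a,
           ROTATE_LEFT = yaw[in_p] <- yaw[in_p] + a,
           ROTATE_RIGHT = yaw[in_p] <- yaw[in_p] - a,
           HOLD = NULL)
  }
  d2r <- pi / 180
  g <- cbind(tan(lateral * d2r), 1, tan(frontal * d2r))
  g <- g / sqrt(rowSums(g^2))
  out <- list(truth = data.frame(t = t, frontal_deg = frontal,
                                 lateral_deg = lateral, yaw_deg = yaw),
              gravity = g)
  if (include_rotations) {
    out$rotations <- vapply(seq_along(t), function(i) {
      rotation_from_angles(frontal[i], lateral[i], yaw[i])
    }, matrix(0, 3, 3))
  }
  structure(out, class = "trunk_trajectory")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize an accelerometer stream from a trajectory
#'
#' Each sample is the device-frame gravity reading of the current
#' orientation, `t(R) %*% (0, g0, 0)`, plus independent Gaussian noise
#' per axis.
#'
#' @param traj `trunk_trajectory`.
#' @param noise_sd per-axis noise standard deviation, m/s^2.
#' @param seed RNG seed for the noise draw (global RNG state is
#'   restored afterwards).
#' @return data.frame `t`, `ax`, `ay`, `az`.
#' @export
synth_accel <- function(traj, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(traj, "trunk_trajectory"), noise_sd >= 0)
  n <- nrow(traj$truth)
  a <- G0 * traj$gravity
  if (noise_sd > 0) {
    a <- a + with_seed(seed, matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3))
  }
  data.frame(t = traj$truth$t, ax = a[, 1], ay = a[, 2], az = a[, 3])
}

#' Scenario for a simulated monitoring stage
#'
#' Defines the statistical conditions of a simulated rehabilitation
#' stage: an upright wearer with episodic trunk deviations arriving as
#' a Poisson process, each a random flexion/extension/bend of random
#' amplitude held until the (condition-dependent) correction latency
#' elapses, plus accelerometer noise. Correction latencies are
#' log-normal: with feedback on, the patient corrects shortly after the
#' first audio directive; with feedback off, self-initiated correction
#' takes substantially longer.
#'
#' @param duration_s stage length, seconds (default 540 s, i.e. 9 min).
#' @param sample_rate_hz accelerometer rate (default 50 Hz).
#' @param engine_rate_hz rate at which the feedback engine evaluates
#'   the smoothed angles (default 10 Hz).
#' @param noise_sd_ms2 per-axis accelerometer noise SD (default 0.2).
#' @param deviation_rate_per_min Poisson arrival rate of deviation
#'   episodes (default 1.5 per minute).
#' @param amplitude_range_deg min/max deviation amplitude (default
#'   10-25 degrees).
#' @param latency_meanlog_on,latency_sdlog_on log-normal parameters of
#'   the post-directive correction latency, feedback on (default
#'   meanlog log(3), sdlog 0.4).
#' @param latency_meanlog_off,latency_sdlog_off same for feedback off
#'   (default meanlog log(15), sdlog 0.5).
#' @param rng_seed default seed for stage simulation.
#' @return object of class `session_scenario`.
#' @export
session_scenario <- function(duration_s = 540,
                             sample_rate_hz = 50,
                             engine_rate_hz = 10,
                             noise_sd_ms2 = 0.2,
                             deviation_rate_per_min = 1.5,
                             amplitude_range_deg = c(10, 25),
                             latency_meanlog_on = log(3),
                             latency_sdlog_on = 0.4,
                             latency_meanlog_off = log(15),
                             latency_sdlog_off = 0.5,
                             rng_seed = 1L) {
  stopifnot(duration_s > 0, sample_rate_hz > 0, engine_rate_hz > 0,
            noise_sd_ms2 >= 0, deviation_rate_per_min >= 0,
            length(amplitude_range_deg) == 2,
            all(amplitude_range_deg >= 0), all(amplitude_range_deg < 90),
            latency_sdlog_on >= 0, latency_sdlog_off >= 0)
  structure(as.list(environment()), class = "session_scenario")
}

#' Read a scenario file (JSON)
#' @param path JSON file whose fields mirror [session_scenario()].
#' @return `session_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("cannot read scenario: no such file: ", path)
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vals <- vals[names(vals) %in% names(formals(session_scenario))]
  do.call(session_scenario, vals)
}

# draw the primitive schedule of one stage
draw_primitives <- function(scenario, cfg, feedback) {
  rate_s <- scenario$deviation_rate_per_min / 60
  lead_in <- 5  # upright at the start: calibration window + settling
  prims <- list()
  cursor <- lead_in
  t_next <- lead_in + if (rate_s > 0) stats::rexp(1, rate_s) else Inf
  while (t_next < scenario$duration_s) {
    if (t_next > cursor) {
      prims[[length(prims) + 1L]] <-
        movement_primitive("HOLD", 0, 0, t_next - cursor, 0)
      cursor <- t_next
    }
    kind <- sample(c("FLEXION", "EXTENSION", "BEND_LEFT", "BEND_RIGHT"), 1)
    amp <- stats::runif(1, scenario$amplitude_range_deg[1],
                        scenario$amplitude_range_deg[2])
    hold <- if (feedback == "on") {
      cfg$tolerance_s + stats::rlnorm(1, scenario$latency_meanlog_on,
                                      scenario$latency_sdlog_on)
    } else {
      stats::rlnorm(1, scenario$latency_meanlog_off,
                    scenario$latency_sdlog_off)
    }
    p <- movement_primitive(kind, amp, stats::runif(1, 0.5, 1.5), hold,
                            stats::runif(1, 0.5, 1.5))
    prims[[length(prims) + 1L]] <- p
    cursor <- cursor + p$rise_s + p$hold_s + p$return_s
    # next arrival after the current movement completes
    t_next <- max(cursor, t_next + stats::rexp(1, rate_s))
  }
  if (cursor < scenario$duration_s) {
    prims[[length(prims) + 1L]] <-
      movement_primitive("HOLD", 0, 0, scenario$duration_s - cursor, 0)
  }
  if (length(prims) == 0) {
    prims <- list(movement_primitive("HOLD", 0, 0, scenario$duration_s, 0))
  }
  prims
}

#' Simulate one monitored stage end to end
#'
#' Generates the wearer's movement schedule, synthesizes the
#' accelerometer stream, smooths it, calibrates from the first second
#' (the wearer starts in their best-at-the-time posture), runs the full
#' feedback engine over the stream and assembles the session log with
#' 1 Hz angle records. A feedback-off stage runs the same engine with
#' every feedback channel silenced, so movements are classified and
#' logged but no feedback events appear.
#'
#' @param scenario `session_scenario`.
#' @param cfg `posture_config`.
#' @param feedback `"on"` or `"off"`.
#' @param subject_id subject identifier for the log header.
#' @param seed stage RNG seed; defaults to the scenario's.
#' @return `session_log`.
#' @export
simulate_stage <- function(scenario = session_scenario(),
                           cfg = posture_config(), feedback = c("on", "off"),
                           subject_id = "S01", seed = scenario$rng_seed) {
  feedback <- match.arg(feedback)
  stage_cfg <- cfg
  if (feedback == "off") {
    stage_cfg$visual_enabled <- FALSE
    stage_cfg$vibration_enabled <- FALSE
    stage_cfg$audio_enabled <- FALSE
  }
  prims <- with_seed(seed, draw_primitives(scenario, cfg, feedback))
  traj <- trajectory(prims, rate = scenario$sample_rate_hz)
  samples <- synth_accel(traj, noise_sd = scenario$noise_sd_ms2,
                         seed = seed + 1L)
  est <- gravity_filter(validate_samples(samples))
  ref <- calibrate(est[est$t <= 1 & est$valid, ])
  est_ok <- est[est$valid, ]
  ang <- deviation_angles(est_ok, ref)

  # engine evaluates at engine_rate_hz, starting after calibration
  step_by <- max(1L, round(scenario$sample_rate_hz / scenario$engine_rate_hz))
  eng_idx <- which(ang$t > 1)
  eng_idx <- eng_idx[seq(1, length(eng_idx), by = step_by)]
  eng_ang <- ang[eng_idx, ]
  run <- run_engine(eng_ang, stage_cfg)

  cal_event <- list(t = 1, kind = "CALIBRATED",
                    payload = if (stage_cfg$audio_enabled) {
                      audio_payload("CALIBRATION_DONE", stage_cfg)
                    } else list(key = "CALIBRATION_DONE"))
  events <- c(list(cal_event), run$events)

  # 1 Hz angle records from the engine-rate stream
  sec <- floor(eng_ang$t)
  keep <- !duplicated(sec)
  angle_records <- data.frame(t = sec[keep],
                              frontal_deg = eng_ang$frontal_deg[keep],
                              lateral_deg = eng_ang$lateral_deg[keep],
                              posture = run$posture[keep])
  session_log(subject_id = subject_id, stage_label = paste0("feedback_", feedback),
              config = stage_cfg, calibration = ref,
              angle_records = angle_records, events = events)
}

#' Simulate a full within-subjects experiment
#'
#' Each subject performs two consecutive stages under the same
#' scenario: first without feedback, then with feedback (each subject
#' serving as their own control).
#'
#' @param n_subjects number of subjects.
#' @param scenario `session_scenario`.
#' @param cfg `posture_config`.
#' @param seed experiment seed; per-stage seeds are derived from it.
#' @return list of `session_log`s (two per subject).
#' @export
simulate_subjects <- function(n_subjects, scenario = session_scenario(),
                              cfg = posture_config(), seed = 1L) {
  logs <- vector("list", 2L * n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    base <- (seed + 7919 * i) %% 2000000000
    logs[[2L * i - 1L]] <- simulate_stage(scenario, cfg, "off", sid,
                                          seed = base)
    logs[[2L * i]] <- simulate_stage(scenario, cfg, "on", sid,
                                     seed = base + 1)
  }
  logs
}
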