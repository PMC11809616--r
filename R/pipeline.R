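#' Monitor a recorded accelerometer stream headlessly
#'
#' The batch analogue of the app's run loop (the app works with the
#' screen off, so the engine is fully headless): validates and smooths
#' the stream, calibrates the best-at-the-time posture from the opening
#' window, runs the feedback engine over the remainder and returns the
#' session log.
#'
#' @param stream a data.frame (`t`,`ax`,`ay`,`az`) or a path readable
#'   by [read_accel_stream()].
#' @param cfg `posture_config`.
#' @param calibration_window_s seconds of the opening stream used for
#'   calibration (default 1 s).
#' @param subject_id,stage_label log header fields.
#' @param engine_rate_hz evaluation rate of the engine over the
#'   smoothed stream; `NULL` evaluates every sample.
#' @return `session_log`.
#' @export
monitor_stream <- function(stream, cfg = posture_config(),
                           calibration_window_s = 1,
                           subject_id = "anonymous",
                           stage_label = "feedback_on",
                           engine_rate_hz = NULL) {
  samples <- if (is.character(stream)) read_accel_stream(stream) else stream
  est <- gravity_filter(validate_samples(samples))
  win <- est[est$t <= est$t[1] + calibration_window_s & est$valid, ]
  ref <- calibrate(win)
  est_ok <- est[est$valid & est$t > est$t[1] + calibration_window_s, ]
  if (nrow(est_ok) == 0) stop("stream ends before the calibration window")
  ang <- deviation_angles(est_ok, ref)
  if (!is.null(engine_rate_hz)) {
    dt <- stats::median(diff(ang$t))
    by <- max(1L, round(1 / (engine_rate_hz * dt)))
    ang <- ang[seq(1, nrow(ang), by = by), ]
  }
  run <- run_engine(ang, cfg)
  cal_event <- list(t = win$t[nrow(win)], kind = "CALIBRATED",
                    payload = if (cfg$audio_enabled) {
                      audio_payload("CALIBRATION_DONE", cfg)
                    } else list(key = "CALIBRATION_DONE"))
  sec <- floor(ang$t)
  keep <- !duplicated(sec)
  angle_records <- data.frame(t = sec[keep],
                              frontal_deg = ang$frontal_deg[keep],
                              lateral_deg = ang$lateral_deg[keep],
                              posture = run$posture[keep])
  session_log(subject_id = subject_id, stage_label = stage_label,
              config = cfg, calibration = ref,
              angle_records = angle_records,
              events = c(list(cal_event), run$events))
}

#' Analyze one or more session logs
#'
#' Computes per-stage metrics for every log and, when both conditions
#' are present, the two-condition comparison (paired t where subjects
#' overlap, plus the summary-statistic Welch test).
#'
#' @param logs list of `session_log`s or character paths.
#' @param min_hold_s maintained-position threshold, seconds.
#' @param metric metric compared across conditions.
#' @return list with `table` (data.frame) and possibly `comparison`.
#' @export
analyze_logs <- function(logs, min_hold_s = 5,
                         metric = "maintained_positions") {
  if (length(logs) == 0) stop("no logs to analyze")
  logs <- lapply(logs, function(lg) {
    if (is.character(lg)) read_session_log(lg) else lg
  })
  tab <- metrics_table(logs, min_hold_s = min_hold_s)
  res <- list(table = tab)
  if (all(c("feedback_on", "feedback_off") %in% tab$stage_label) &&
      sum(tab$stage_label == "feedback_on") >= 2 &&
      sum(tab$stage_label == "feedback_off") >= 2) {
    res$comparison <- compare_conditions(tab, metric = metric)
  }
  res
}

#' One-line textual summary of a comparison
#' @param cmp result of [compare_conditions()].
#' @return character scalar.
#' @export
format_comparison <- function(cmp) {
  s <- sprintf(
    "%s: feedback_on mean %.2f (SD %.2f, n=%d) vs feedback_off mean %.2f (SD %.2f, n=%d); Welch t=%.2f, df=%.1f, p=%.3g",
    cmp$metric, cmp$feedback_on$mean, cmp$feedback_on$sd, cmp$feedback_on$n,
    cmp$feedback_off$mean, cmp$feedback_off$sd, cmp$feedback_off$n,
    cmp$welch$t, cmp$welch$df, cmp$welch$p)
  if (!is.null(cmp$paired)) {
    s <- paste0(s, sprintf("; paired t=%.2f, df=%d, p=%.3g",
                           cmp$paired$t, cmp$paired$df, cmp$paired$p))
  }
  s
}
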