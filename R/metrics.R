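#' Segment a stage into posture episodes
#'
#' Partitions the stage into maximal runs of constant posture state from
#' the 1 Hz angle records. An episode's end is the start of the next
#' episode; the last episode ends at the final record.
#'
#' @param log `session_log` with non-empty angle records.
#' @return data.frame with columns `state`, `start`, `end`,
#'   `duration_s`.
#' @export
episodes <- function(log) {
  ar <- log$angle_records
  if (is.null(ar) || nrow(ar) == 0) stop("empty log: no angle records")
  st <- ar$posture
  starts <- c(1L, which(st[-1] != st[-length(st)]) + 1L)
  ends <- c(starts[-1], length(st) + 1L)
  out <- data.frame(state = st[starts],
                    start = ar$t[starts],
                    end = c(ar$t[starts[-1]], ar$t[nrow(ar)]))
  out$duration_s <- out$end - out$start
  out
}

#' Per-stage session metrics
#'
#' Derives the study's outcome measures from a stage log:
#' `maintained_positions` counts in-posture episodes held at least
#' `min_hold_s` seconds (the best-at-the-time postures the patient could
#' maintain); `corrective_movements` counts completed returns to posture
#' (OUT to IN transitions); `time_in_posture_fraction` is the share of
#' stage time spent in posture. `out_episodes` (every out-of-posture
#' episode, ended or not) is emitted as a configurable alternative
#' movement count.
#'
#' @param log `session_log`.
#' @param min_hold_s minimum duration for an episode to count as a
#'   maintained position; default 5 s.
#' @return list of class `session_metrics`.
#' @export
session_metrics <- function(log, min_hold_s = 5) {
  ep <- episodes(log)
  ar <- log$angle_records
  stage_s <- ar$t[nrow(ar)] - ar$t[1]
  in_ep <- ep[ep$state == "IN", , drop = FALSE]
  out_ep <- ep[ep$state == "OUT", , drop = FALSE]
  n_ep <- nrow(ep)
  # an OUT episode "ends within the stage" when an IN episode follows it
  completed_out <- sum(ep$state == "OUT" & seq_len(n_ep) < n_ep)
  structure(list(
    subject_id = log$header$subject_id,
    stage_label = log$header$stage_label,
    stage_duration_min = stage_s / 60,
    maintained_positions = sum(in_ep$duration_s >= min_hold_s),
    corrective_movements = completed_out,
    out_episodes = nrow(out_ep),
    time_in_posture_fraction = if (stage_s > 0) {
      sum(in_ep$duration_s) / stage_s
    } else as.numeric(nrow(in_ep) > 0),
    in_episode_durations_s = in_ep$duration_s,
    out_episode_durations_s = out_ep$duration_s,
    min_hold_s = min_hold_s), class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    "Session metrics [%s, %s]\n  stage duration: %.2f min\n  maintained positions (>= %g s): %d\n  corrective movements: %d\n  time in posture: %.1f%%\n",
    x$subject_id, x$stage_label, x$stage_duration_min, x$min_hold_s,
    x$maintained_positions, x$corrective_movements,
    100 * x$time_in_posture_fraction))
  invisible(x)
}

#' Group summary statistics
#'
#' @param mean group mean.
#' @param sd group standard deviation (non-negative).
#' @param n group size (at least 2).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop("group summary needs n >= 2")
  if (sd < 0) stop("sd must be non-negative")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Welch's two-sample t test from summary statistics
#'
#' Unequal-variance two-sample t test computed directly from group
#' means, SDs and sizes, with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p value. This is the desk check applicable when
#' only printed summaries, not raw data, are available.
#'
#' @param a,b `group_summary` objects (see [group_summary()]).
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_t_from_summaries(group_summary(13.1, 7.12, 40),
#'                        group_summary(4.2, 3.97, 40))
#' @export
welch_t_from_summaries <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se2 <- va + vb
  if (se2 == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    stop("degenerate test: both groups have zero variance and unequal means")
  }
  t_stat <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

#' Paired two-tailed t test on per-subject stage pairs
#'
#' Within-subjects comparison of a metric measured in both stages of
#' each subject's session (feedback on vs off).
#'
#' @param metric_on,metric_off numeric vectors, one value per subject,
#'   same order.
#' @return list with `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(metric_on, metric_off) {
  if (length(metric_on) != length(metric_off)) {
    stop("paired test needs equal-length vectors")
  }
  if (length(metric_on) < 2) stop("paired test needs at least 2 pairs")
  d <- metric_on - metric_off
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1,
                                 mean_difference = 0))
    stop("degenerate paired test: zero variance of non-zero differences")
  }
  ht <- stats::t.test(metric_on, metric_off, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Tabulate metrics for several logs
#'
#' @param logs list of `session_log` objects.
#' @param min_hold_s passed to [session_metrics()].
#' @return data.frame, one row per log.
#' @export
metrics_table <- function(logs, min_hold_s = 5) {
  rows <- lapply(logs, function(lg) {
    m <- session_metrics(lg, min_hold_s = min_hold_s)
    data.frame(subject_id = m$subject_id, stage_label = m$stage_label,
               stage_duration_min = m$stage_duration_min,
               maintained_positions = m$maintained_positions,
               corrective_movements = m$corrective_movements,
               out_episodes = m$out_episodes,
               time_in_posture_fraction = m$time_in_posture_fraction,
               min_hold_s = m$min_hold_s)
  })
  do.call(rbind, rows)
}

#' Two-condition comparison across subjects
#'
#' Pairs each subject's feedback_on and feedback_off stages and compares
#' a metric with both the paired t test (the within-subjects analysis)
#' and the summary-statistic Welch test (the desk-reproducible check).
#'
#' @param tab data.frame from [metrics_table()] holding both stages per
#'   subject.
#' @param metric column name to compare; default
#'   `"maintained_positions"`.
#' @return list with `metric`, per-condition `group_summary`s, `welch`,
#'   and `paired` (when every subject has both stages).
#' @export
compare_conditions <- function(tab, metric = "maintained_positions") {
  stopifnot(metric %in% names(tab))
  on <- tab[tab$stage_label == "feedback_on", ]
  off <- tab[tab$stage_label == "feedback_off", ]
  if (nrow(on) < 2 || nrow(off) < 2) {
    stop("need at least 2 logs per condition")
  }
  a <- group_summary(mean(on[[metric]]), stats::sd(on[[metric]]), nrow(on))
  b <- group_summary(mean(off[[metric]]), stats::sd(off[[metric]]), nrow(off))
  res <- list(metric = metric, feedback_on = a, feedback_off = b,
              welch = welch_t_from_summaries(a, b))
  shared <- intersect(on$subject_id, off$subject_id)
  if (length(shared) >= 2 && nrow(on) == nrow(off)) {
    on_v <- on[[metric]][match(shared, on$subject_id)]
    off_v <- off[[metric]][match(shared, off$subject_id)]
    res$paired <- paired_t(on_v, off_v)
  }
  res
}
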