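#' Feedback engine configuration
#'
#' Bundles the per-patient monitoring settings a therapist enters before
#' a stage: per-plane deviation thresholds (degrees), the tolerance
#' duration a patient may stay beyond them before audio guidance starts
#' (seconds), feedback channel toggles and language.
#'
#' @param frontal_threshold_deg positive; allowed forward/backward lean.
#' @param lateral_threshold_deg positive; allowed sideways lean.
#' @param tolerance_s non-negative; delay before the first directive.
#' @param vibration_enabled emit VIBRATION events on deviation.
#' @param audio_enabled emit AUDIO_* events (directives, praise,
#'   congratulations).
#' @param visual_enabled emit COLOR_* events; turning all three channels
#'   off runs the engine in silent-recording mode (movements are still
#'   classified and logged).
#' @param language one of `"en"`, `"es"`, `"pt"`.
#' @param hysteresis_deg non-negative, smaller than both thresholds;
#'   re-entering posture requires deviations at or below threshold minus
#'   hysteresis, preventing chatter at the boundary. Default 0.
#' @param directive_repeat_s interval between repeated directives while
#'   the patient stays out of posture; defaults to `tolerance_s`.
#' @param praise_interval_s praise after this much continuous in-posture
#'   time; default 300 s (5 minutes).
#' @param rng_seed integer seed for the congratulation-variant draw, so
#'   identical streams yield identical event lists.
#' @return object of class `posture_config`.
#' @export
posture_config <- function(frontal_threshold_deg = 5,
                           lateral_threshold_deg = 5,
                           tolerance_s = 3,
                           vibration_enabled = TRUE,
                           audio_enabled = TRUE,
                           visual_enabled = TRUE,
                           language = "en",
                           hysteresis_deg = 0,
                           directive_repeat_s = NULL,
                           praise_interval_s = 300,
                           rng_seed = 1L) {
  if (is.null(directive_repeat_s)) directive_repeat_s <- max(tolerance_s, 1e-9)
  cfg <- list(frontal_threshold_deg = frontal_threshold_deg,
              lateral_threshold_deg = lateral_threshold_deg,
              tolerance_s = tolerance_s,
              vibration_enabled = isTRUE(vibration_enabled),
              audio_enabled = isTRUE(audio_enabled),
              visual_enabled = isTRUE(visual_enabled),
              language = language,
              hysteresis_deg = hysteresis_deg,
              directive_repeat_s = directive_repeat_s,
              praise_interval_s = praise_interval_s,
              rng_seed = as.integer(rng_seed))
  validate_posture_config(cfg)
  structure(cfg, class = "posture_config")
}

validate_posture_config <- function(cfg) {
  stopifnot(cfg$frontal_threshold_deg > 0,
            cfg$lateral_threshold_deg > 0,
            cfg$tolerance_s >= 0,
            cfg$praise_interval_s > 0,
            cfg$directive_repeat_s > 0,
            cfg$hysteresis_deg >= 0)
  if (cfg$hysteresis_deg >= min(cfg$frontal_threshold_deg,
                                cfg$lateral_threshold_deg)) {
    stop("hysteresis_deg must be smaller than both thresholds")
  }
  if (!cfg$language %in% LANGUAGES) {
    stop("unknown language: ", cfg$language)
  }
  invisible(cfg)
}

#' Read an engine configuration file
#'
#' Accepts JSON (an object with `posture_config` field names) or
#' key=value lines. All fields are optional; unset fields keep their
#' defaults.
#'
#' @param path config file path.
#' @param ... overrides applied after the file (e.g. from CLI flags).
#' @return `posture_config`.
#' @export
read_posture_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("cannot read config: no such file: ", path)
    txt <- readLines(path, warn = FALSE)
    if (any(grepl("^\\s*\\{", txt))) {
      vals <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                 simplifyVector = TRUE)
    } else {
      kv <- txt[grepl("=", txt, fixed = TRUE)]
      for (line in kv) {
        parts <- strsplit(line, "=", fixed = TRUE)[[1]]
        key <- trimws(parts[1]); val <- trimws(paste(parts[-1], collapse = "="))
        num <- suppressWarnings(as.numeric(val))
        vals[[key]] <- if (!is.na(num)) num
          else if (val %in% c("true", "false")) val == "true" else val
      }
    }
  }
  vals <- utils::modifyList(vals, list(...))
  allowed <- names(formals(posture_config))
  vals <- vals[names(vals) %in% allowed]
  do.call(posture_config, vals)
}

#' Fresh engine state
#'
#' The engine starts paused and in posture; [engine_control()] with
#' `"play"` begins monitoring.
#'
#' @param cfg `posture_config` (seeds the congratulation RNG).
#' @param t stage time of creation, seconds.
#' @return object of class `engine_state`.
#' @export
engine_state <- function(cfg = posture_config(), t = 0) {
  seed <- cfg$rng_seed %% 2147483646L + 1L  # Lehmer state in [1, 2^31-2]
  structure(list(monitoring = FALSE,
                 posture = "IN",
                 entered_at = t,
                 last_praise_at = NA_real_,
                 next_directive_at = NA_real_,
                 rng_state = seed),
            class = "engine_state")
}

# Lehmer / Park-Miller step: products stay below 2^53 so doubles are exact
lehmer_next <- function(s) (16807 * s) %% 2147483647

#' Classify deviation angles against the thresholds
#'
#' Out of posture when either plane exceeds its threshold; when already
#' out, re-entry requires both planes at or below threshold minus
#' hysteresis.
#'
#' @param frontal_deg,lateral_deg signed deviations, degrees.
#' @param cfg `posture_config`.
#' @param current `"IN"` or `"OUT"`.
#' @return `"IN"` or `"OUT"`.
#' @export
classify_posture <- function(frontal_deg, lateral_deg, cfg, current = "IN") {
  af <- abs(frontal_deg); al <- abs(lateral_deg)
  if (af > cfg$frontal_threshold_deg || al > cfg$lateral_threshold_deg) {
    return("OUT")
  }
  if (current == "OUT") {
    h <- cfg$hysteresis_deg
    if (af > cfg$frontal_threshold_deg - h || al > cfg$lateral_threshold_deg - h) {
      return("OUT")
    }
  }
  "IN"
}

#' Corrective directive for an out-of-posture deviation
#'
#' Picks the plane with the larger deviation-to-threshold ratio (tie
#' goes to the frontal plane) and returns the opposite-direction
#' instruction key: a forward lean asks the patient to lean backward,
#' a rightward lean to lean left, and so on.
#'
#' @inheritParams classify_posture
#' @return A message key (see [message_keys()]).
#' @export
directive_for <- function(frontal_deg, lateral_deg, cfg) {
  if (classify_posture(frontal_deg, lateral_deg, cfg, "IN") == "IN") {
    stop("no directive needed: posture within thresholds")
  }
  rf <- abs(frontal_deg) / cfg$frontal_threshold_deg
  rl <- abs(lateral_deg) / cfg$lateral_threshold_deg
  if (rf >= rl) {
    if (frontal_deg > 0) "LEAN_BACKWARD" else "LEAN_FORWARD"
  } else {
    if (lateral_deg > 0) "LEAN_LEFT" else "LEAN_RIGHT"
  }
}

audio_payload <- function(key, cfg) {
  list(key = key, language = cfg$language,
       text = resolve_message(key, cfg$language))
}

#' Advance the feedback engine by one observation
#'
#' The engine's transition rules: leaving posture turns the screen red
#' and fires a vibration, and schedules the first audio directive
#' `tolerance_s` later; while out of posture, directives repeat every
#' `directive_repeat_s`; returning to posture turns the screen green and
#' plays a randomly varied congratulation; every `praise_interval_s` of
#' continuous in-posture time earns a praise message. Channels that are
#' disabled in the config never emit.
#'
#' @param state `engine_state` with `monitoring = TRUE`.
#' @param frontal_deg,lateral_deg current deviation, degrees.
#' @param t stage time, seconds (non-decreasing across calls).
#' @param cfg `posture_config`.
#' @return list with `state` (updated) and `events` (possibly empty
#'   list of feedback events, each `list(t, kind, payload)`).
#' @export
engine_step <- function(state, frontal_deg, lateral_deg, t, cfg) {
  if (!state$monitoring) stop("engine paused")
  events <- list()
  new_posture <- classify_posture(frontal_deg, lateral_deg, cfg, state$posture)

  if (state$posture == "IN" && new_posture == "OUT") {
    if (cfg$visual_enabled) {
      events[[length(events) + 1L]] <- list(t = t, kind = "COLOR_RED",
                                            payload = NULL)
    }
    if (cfg$vibration_enabled) {
      events[[length(events) + 1L]] <- list(t = t, kind = "VIBRATION",
                                            payload = NULL)
    }
    state$posture <- "OUT"
    state$entered_at <- t
    state$next_directive_at <- if (cfg$audio_enabled) t + cfg$tolerance_s
                               else NA_real_
  } else if (state$posture == "OUT" && new_posture == "IN") {
    if (cfg$visual_enabled) {
      events[[length(events) + 1L]] <- list(t = t, kind = "COLOR_GREEN",
                                            payload = NULL)
    }
    if (cfg$audio_enabled) {
      state$rng_state <- lehmer_next(state$rng_state)
      variant <- state$rng_state %% N_CONGRATULATIONS + 1
      key <- paste0("CONGRATULATION_", variant)
      events[[length(events) + 1L]] <- list(t = t, kind = "AUDIO_CONGRATULATION",
                                            payload = audio_payload(key, cfg))
    }
    state$posture <- "IN"
    state$entered_at <- t
    state$last_praise_at <- NA_real_
    state$next_directive_at <- NA_real_
  }

  if (state$posture == "OUT" && cfg$audio_enabled &&
      !is.na(state$next_directive_at) && t >= state$next_directive_at) {
    key <- directive_for(frontal_deg, lateral_deg, cfg)
    events[[length(events) + 1L]] <- list(t = t, kind = "AUDIO_DIRECTIVE",
                                          payload = audio_payload(key, cfg))
    state$next_directive_at <- state$next_directive_at + cfg$directive_repeat_s
  }

  if (state$posture == "IN" && cfg$audio_enabled) {
    anchor <- max(state$entered_at, state$last_praise_at, na.rm = TRUE)
    if (t - anchor >= cfg$praise_interval_s) {
      events[[length(events) + 1L]] <- list(
        t = t, kind = "AUDIO_PRAISE",
        payload = audio_payload("PRAISE_MAINTAINED", cfg))
      state$last_praise_at <- t
    }
  }

  list(state = state, events = events)
}

#' Play/pause/settings control commands
#'
#' Every interaction is logged: starting monitoring emits
#' MONITORING_STARTED plus the initial green screen; pausing or stopping
#' emits MONITORING_PAUSED; a settings update emits SETTINGS_CHANGED
#' carrying old and new values and returns the updated config.
#'
#' @param state `engine_state`.
#' @param command one of `"play"`, `"pause"`, `"stop"`,
#'   `"update_settings"`.
#' @param t stage time, seconds.
#' @param cfg `posture_config`.
#' @param payload for `update_settings`: named list of fields to change.
#' @return list with `state`, `config`, `events`.
#' @export
engine_control <- function(state, command, t, cfg, payload = NULL) {
  events <- list()
  if (command == "play") {
    state$monitoring <- TRUE
    state$entered_at <- t
    events[[1L]] <- list(t = t, kind = "MONITORING_STARTED", payload = NULL)
    if (cfg$visual_enabled) {
      events[[2L]] <- list(t = t, kind = "COLOR_GREEN", payload = NULL)
    }
  } else if (command %in% c("pause", "stop")) {
    state$monitoring <- FALSE
    events[[1L]] <- list(t = t, kind = "MONITORING_PAUSED", payload = NULL)
  } else if (command == "update_settings") {
    stopifnot(is.list(payload), length(payload) > 0, !is.null(names(payload)))
    changed <- list()
    for (field in names(payload)) {
      if (!field %in% names(cfg)) stop("unknown setting: ", field)
      changed[[field]] <- list(old = cfg[[field]], new = payload[[field]])
      cfg[[field]] <- payload[[field]]
    }
    validate_posture_config(cfg)
    events[[1L]] <- list(t = t, kind = "SETTINGS_CHANGED",
                         payload = list(changed = changed))
  } else {
    stop("unknown command: ", command)
  }
  list(state = state, config = cfg, events = events)
}

#' Run the engine over a deviation-angle stream
#'
#' Convenience driver: starts monitoring at the first timestamp (unless
#' an already-monitoring state is supplied), steps through every record
#' and collects all events plus the per-record posture classification.
#'
#' @param angles data.frame with columns `t`, `frontal_deg`,
#'   `lateral_deg`, time-ordered.
#' @param cfg `posture_config`.
#' @param state optional `engine_state` to continue from.
#' @return list with `events`, `posture` (character vector, one entry
#'   per record), `state`.
#' @export
run_engine <- function(angles, cfg, state = NULL) {
  n <- nrow(angles)
  events <- vector("list", 64L); n_ev <- 0L
  push <- function(evs) {
    for (e in evs) {
      n_ev <<- n_ev + 1L
      if (n_ev > length(events)) length(events) <<- 2L * n_ev
      events[[n_ev]] <<- e
    }
  }
  if (is.null(state)) {
    state <- engine_state(cfg, t = if (n > 0) angles$t[1] else 0)
    ctrl <- engine_control(state, "play",
                           t = if (n > 0) angles$t[1] else 0, cfg)
    state <- ctrl$state
    push(ctrl$events)
  }
  posture <- character(n)
  tt <- angles$t; ff <- angles$frontal_deg; ll <- angles$lateral_deg
  for (i in seq_len(n)) {
    res <- engine_step(state, ff[i], ll[i], tt[i], cfg)
    state <- res$state
    if (length(res$events)) push(res$events)
    posture[i] <- state$posture
  }
  list(events = events[seq_len(n_ev)], posture = posture, state = state)
}
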