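SCHEMA_NAMESPACE <- "trunksense"
SCHEMA_NAME <- "posture-session-log"
SCHEMA_VERSION <- "1.0"

EVENT_KINDS <- c("COLOR_GREEN", "COLOR_RED", "VIBRATION", "AUDIO_DIRECTIVE",
                 "AUDIO_PRAISE", "AUDIO_CONGRATULATION", "CALIBRATED",
                 "SETTINGS_CHANGED", "MONITORING_STARTED", "MONITORING_PAUSED")

#' Assemble a session log
#'
#' The complete record of one monitored stage: a header identifying the
#' subject, stage and the configuration and calibration in force, the
#' 1 Hz angle records with their posture classification, and every
#' feedback/control event with its timestamp. Serialized via
#' [write_session_log()] in an OpenMHealth-style header/body envelope.
#'
#' @param subject_id character subject identifier.
#' @param stage_label `"feedback_on"` or `"feedback_off"`.
#' @param config the `posture_config` the stage ran under.
#' @param calibration the `calibration_reference` used.
#' @param angle_records data.frame `t`, `frontal_deg`, `lateral_deg`,
#'   `posture` at 1 Hz.
#' @param events list of event records `list(t, kind, payload)`.
#' @param recorded_at ISO-8601 wall-clock timestamp of the recording
#'   (injectable; stage-internal times stay relative seconds).
#' @return object of class `session_log`.
#' @export
session_log <- function(subject_id, stage_label, config, calibration,
                        angle_records, events = list(),
                        recorded_at = "1970-01-01T00:00:00Z") {
  log <- structure(list(
    header = list(schema_version = SCHEMA_VERSION,
                  subject_id = as.character(subject_id),
                  stage_label = stage_label,
                  recorded_at = recorded_at,
                  config = unclass(config),
                  calibration = list(r0 = as.numeric(calibration$r0),
                                     created_at = calibration$created_at)),
    angle_records = angle_records,
    events = events), class = "session_log")
  validate_session_log(log)
  log
}

#' Validate a session log's invariants
#'
#' Structural validation with named-field diagnostics: required header
#' fields, known stage label and event kinds, numeric non-decreasing
#' timestamps, posture values, calibration unit vector.
#'
#' @param log a `session_log` (or an untrusted list with its shape).
#' @return invisibly `TRUE`; otherwise stops with a message naming the
#'   offending field.
#' @export
validate_session_log <- function(log) {
  h <- log$header
  if (is.null(h)) stop("invalid log: missing field 'header'")
  for (f in c("schema_version", "subject_id", "stage_label", "config",
              "calibration")) {
    if (is.null(h[[f]])) stop("invalid log: missing field 'header.", f, "'")
  }
  if (!identical(h$schema_version, SCHEMA_VERSION)) {
    stop("invalid log: unknown schema version in field 'header.schema_version': ",
         h$schema_version)
  }
  if (!h$stage_label %in% c("feedback_on", "feedback_off")) {
    stop("invalid log: field 'header.stage_label' must be feedback_on or ",
         "feedback_off, got: ", h$stage_label)
  }
  r0 <- h$calibration$r0
  if (is.null(r0) || length(r0) != 3 || !is.numeric(r0)) {
    stop("invalid log: field 'header.calibration.r0' must be 3 numbers")
  }
  if (abs(sqrt(sum(r0^2)) - 1) > 1e-6) {
    stop("invalid log: field 'header.calibration.r0' is not a unit vector")
  }
  ar <- log$angle_records
  if (is.null(ar) || !is.data.frame(ar)) {
    stop("invalid log: missing field 'angle_records'")
  }
  for (f in c("t", "frontal_deg", "lateral_deg", "posture")) {
    if (!f %in% names(ar)) {
      stop("invalid log: missing field 'angle_records.", f, "'")
    }
  }
  if (!is.numeric(ar$t) || anyNA(ar$t)) {
    stop("invalid log: field 'angle_records.t' must be numeric")
  }
  if (nrow(ar) > 1 && any(diff(ar$t) < 0)) {
    stop("invalid log: field 'angle_records.t' has decreasing timestamps")
  }
  if (!all(ar$posture %in% c("IN", "OUT"))) {
    stop("invalid log: field 'angle_records.posture' has values outside IN/OUT")
  }
  if (!is.list(log$events)) stop("invalid log: missing field 'events'")
  ev_t <- vapply(log$events, function(e) {
    if (is.null(e$kind)) stop("invalid log: missing field 'events.kind'")
    if (!e$kind %in% EVENT_KINDS) {
      stop("invalid log: unknown event kind in field 'events.kind': ", e$kind)
    }
    if (is.null(e$t) || !is.numeric(e$t)) {
      stop("invalid log: field 'events.t' must be numeric")
    }
    as.numeric(e$t)
  }, numeric(1))
  if (length(ev_t) > 1 && any(diff(ev_t) < 0)) {
    stop("invalid log: field 'events.t' has decreasing timestamps")
  }
  invisible(TRUE)
}

#' Serialize a session log to JSON
#'
#' Writes the OpenMHealth-style envelope: a `header` (schema id,
#' acquisition metadata, configuration and calibration snapshots) and a
#' `body` (angle records and events). Keys are written in a stable
#' order and numbers at full precision, so identical logs serialize to
#' identical documents. The log's invariants are checked before writing.
#'
#' @param log `session_log`.
#' @param path destination file; `NULL` returns the JSON text.
#' @return the path, or the JSON string when `path` is `NULL`.
#' @export
write_session_log <- function(log, path = NULL) {
  validate_session_log(log)
  h <- log$header
  doc <- list(
    header = list(
      schema_id = list(namespace = SCHEMA_NAMESPACE, name = SCHEMA_NAME,
                       version = h$schema_version),
      subject_id = h$subject_id,
      stage_label = h$stage_label,
      recorded_at = h$recorded_at,
      config = h$config,
      calibration = h$calibration),
    body = list(
      angle_records = log$angle_records,
      events = lapply(log$events, function(e) {
        out <- list(t = e$t, kind = e$kind)
        if (!is.null(e$payload)) out$payload <- e$payload
        out
      })))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

as_scalar_num <- function(x) if (is.null(x)) NULL else as.numeric(x[[1]])

# restore a parsed payload (nested lists of scalars) to canonical types
restore_payload <- function(p) {
  if (is.null(p)) return(NULL)
  rapply(p, function(x) x, how = "replace")
}

#' Parse a session log document
#'
#' Inverse of [write_session_log()]: `read_session_log(write_session_log(x))`
#' reproduces `x`. Schema violations fail with a diagnostic naming the
#' offending field; unknown schema versions are rejected.
#'
#' @param path a file path, or a JSON string.
#' @return `session_log`.
#' @export
read_session_log <- function(path) {
  txt <- if (grepl("^\\s*\\{", path[1])) {
    path
  } else {
    if (!file.exists(path)) stop("cannot read log: no such file: ", path)
    paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    stop("invalid log: document is not parseable JSON (",
                         conditionMessage(e), ")")
                  })
  h <- doc$header
  if (is.null(h)) stop("invalid log: missing field 'header'")
  sid <- h$schema_id
  if (is.null(sid) || is.null(sid$version)) {
    stop("invalid log: missing field 'header.schema_id.version'")
  }
  if (!identical(sid$version, SCHEMA_VERSION)) {
    stop("invalid log: unknown schema version in field ",
         "'header.schema_id.version': ", sid$version)
  }
  body <- doc$body
  if (is.null(body) || is.null(body$angle_records)) {
    stop("invalid log: missing field 'body.angle_records'")
  }
  ar <- body$angle_records
  angle_records <- data.frame(
    t = vapply(ar, function(r) {
      if (is.null(r$t) || !is.numeric(r$t)) {
        stop("invalid log: field 'angle_records.t' must be numeric")
      }
      as.numeric(r$t)
    }, numeric(1)),
    frontal_deg = vapply(ar, function(r) as.numeric(r$frontal_deg), numeric(1)),
    lateral_deg = vapply(ar, function(r) as.numeric(r$lateral_deg), numeric(1)),
    posture = vapply(ar, function(r) as.character(r$posture), character(1)))
  events <- lapply(body$events, function(e) {
    list(t = as_scalar_num(e$t), kind = e$kind,
         payload = restore_payload(e$payload))
  })
  cfg <- h$config
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  config <- structure(cfg, class = "posture_config")
  calibration <- structure(
    list(r0 = vapply(h$calibration$r0, as.numeric, numeric(1)),
         created_at = h$calibration$created_at),
    class = "calibration_reference")
  session_log(subject_id = h$subject_id, stage_label = h$stage_label,
              config = config, calibration = calibration,
              angle_records = angle_records, events = events,
              recorded_at = h$recorded_at)
}
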