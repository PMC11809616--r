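#' @keywords internal
"_PACKAGE"

#' Standard gravity (m/s^2)
#'
#' The conventional standard acceleration of free fall, used to validate
#' accelerometer magnitudes and to synthesize gravity readings.
#' @export
G0 <- 9.80665

#' Flag implausible accelerometer samples
#'
#' A chest-worn accelerometer at quasi-static trunk speeds should read a
#' specific force close to gravity. Samples whose magnitude falls below
#' 0.5*g0 (free-fall regime) or above 3*g0 (impact/shake) are flagged
#' invalid; they are kept in the stream but excluded from gravity
#' smoothing downstream.
#'
#' @param samples data.frame with columns `t`, `ax`, `ay`, `az`
#'   (seconds since stage start, m/s^2, device frame). `t` must be
#'   strictly increasing.
#' @return The same data.frame with a logical `valid` column.
#' @examples
#' validate_samples(data.frame(t = 0, ax = 0, ay = 9.81, az = 0))
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("t", "ax", "ay", "az") %in% names(samples)))
  if (nrow(samples) > 1 && any(diff(samples$t) <= 0)) {
    stop("sample timestamps must be strictly increasing")
  }
  mag <- sqrt(samples$ax^2 + samples$ay^2 + samples$az^2)
  samples$valid <- mag >= 0.5 * G0 & mag <= 3 * G0
  samples
}

#' Smooth a raw accelerometer stream into a gravity estimate
#'
#' Applies a per-axis exponential moving average (EMA), the causal,
#' constant-memory smoother suited to a low-end phone. The EMA is seeded
#' with the first valid sample; invalid samples (see
#' [validate_samples()]) do not update the average but carry the last
#' estimate forward. Samples before the first valid one yield
#' `valid = FALSE` estimates.
#'
#' @param samples data.frame as accepted by [validate_samples()]; a
#'   `valid` column is computed if absent.
#' @param alpha smoothing factor in (0, 1]; the default 0.2 is tuned for
#'   50 Hz input (time constant about 0.1 s).
#' @return data.frame with columns `t`, `gx`, `gy`, `gz`, `valid`.
#' @export
gravity_filter <- function(samples, alpha = 0.2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1)
  if (!"valid" %in% names(samples)) samples <- validate_samples(samples)
  n <- nrow(samples)
  out <- data.frame(t = samples$t, gx = NA_real_, gy = NA_real_,
                    gz = NA_real_, valid = FALSE)
  if (n == 0) return(out)
  ok <- which(samples$valid)
  if (length(ok) == 0) return(out)

  ema1 <- function(x) {
    # y_k = (1-alpha) y_{k-1} + alpha x_k, seeded with x_1
    if (length(x) == 1) return(x)
    c(x[1], stats::filter(alpha * x[-1], 1 - alpha,
                          method = "recursive", init = x[1]))
  }
  gx <- ema1(samples$ax[ok]); gy <- ema1(samples$ay[ok]); gz <- ema1(samples$az[ok])

  # index of the latest valid sample at or before each position
  idx <- cumsum(samples$valid)
  have <- idx > 0
  out$gx[have] <- gx[idx[have]]
  out$gy[have] <- gy[idx[have]]
  out$gz[have] <- gz[idx[have]]
  out$valid <- have
  out
}

wrap_deg <- function(x) x - 360 * ceiling((x - 180) / 360)

#' Calibrate the reference posture
#'
#' Registers the wearer's current best-at-the-time posture: the
#' normalized mean gravity direction over a short window becomes the
#' reference against which all deviation angles are measured. The
#' reference persists until a new calibration replaces it.
#'
#' @param estimates data.frame from [gravity_filter()]; typically the
#'   last second of estimates.
#' @param created_at ISO-8601 timestamp recorded with the reference
#'   (injectable so pipelines stay deterministic).
#' @return An object of class `calibration_reference`: list with unit
#'   vector `r0` and `created_at`.
#' @export
calibrate <- function(estimates, created_at = "1970-01-01T00:00:00Z") {
  ok <- !is.na(estimates$valid) & estimates$valid
  if (!any(ok)) stop("cannot calibrate: no valid gravity estimate in window")
  m <- c(mean(estimates$gx[ok]), mean(estimates$gy[ok]), mean(estimates$gz[ok]))
  nm <- sqrt(sum(m^2))
  if (nm == 0) stop("cannot calibrate: mean gravity direction is zero")
  structure(list(r0 = m / nm, created_at = created_at),
            class = "calibration_reference")
}

#' Signed trunk deviation angles relative to the calibrated posture
#'
#' Computes per-plane projected angles from the gravity direction.
#' Device-frame convention: phone in portrait on the sternum, screen
#' outward; +y toward the head, +x toward the wearer's right, +z out of
#' the screen, so an upright wearer reads approximately (0, +g0, 0).
#' Frontal deviation is the in-plane angle atan2(gz, gy) minus the same
#' angle of the reference (positive = leaning forward); lateral is
#' atan2(gx, gy) likewise (positive = leaning toward the wearer's
#' right). Each is wrapped to (-180, 180]. Axial (yaw) rotation about
#' the gravity axis leaves gravity unchanged and is therefore invisible.
#'
#' @param estimates data.frame from [gravity_filter()] (or any frame
#'   with `gx`,`gy`,`gz`,`valid`).
#' @param ref a `calibration_reference`.
#' @return data.frame with columns `t` (if present in input),
#'   `frontal_deg`, `lateral_deg`.
#' @export
deviation_angles <- function(estimates, ref) {
  stopifnot(inherits(ref, "calibration_reference"))
  if (any(is.na(estimates$valid)) || !all(estimates$valid)) {
    stop("no gravity estimate: invalid estimates passed to deviation_angles")
  }
  r0 <- ref$r0
  f0 <- atan2(r0[3], r0[2]) * 180 / pi
  l0 <- atan2(r0[1], r0[2]) * 180 / pi
  frontal <- wrap_deg(atan2(estimates$gz, estimates$gy) * 180 / pi - f0)
  lateral <- wrap_deg(atan2(estimates$gx, estimates$gy) * 180 / pi - l0)
  out <- data.frame(frontal_deg = frontal, lateral_deg = lateral)
  if ("t" %in% names(estimates)) out <- cbind(t = estimates$t, out)
  out
}

#' Read an accelerometer stream file
#'
#' Accepts CSV with header `t,ax,ay,az` or JSON-lines with the same
#' keys (seconds, m/s^2).
#'
#' @param path file path.
#' @return data.frame with columns `t`, `ax`, `ay`, `az`.
#' @export
read_accel_stream <- function(path) {
  if (!file.exists(path)) stop("cannot read stream: no such file: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*\\{", first)) {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(r[c("t", "ax", "ay", "az")])
    }))
  } else {
    df <- utils::read.csv(path)
  }
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    stop("stream file must provide columns t, ax, ay, az")
  }
  df[, need]
}

#' Write an accelerometer stream as CSV
#' @param samples data.frame with columns `t`, `ax`, `ay`, `az`.
#' @param path destination file.
#' @export
write_accel_stream <- function(samples, path) {
  utils::write.csv(samples[, c("t", "ax", "ay", "az")], path, row.names = FALSE)
  invisible(path)
}
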