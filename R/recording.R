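EXCITATION_TYPES <- c("pendulum_1cm", "pendulum_2cm", "drop_large",
                      "drop_small", "other")

#' Recording metadata
#'
#' Provenance attached to a calibrated acceleration trace: identifiers,
#' excitation test, replicate, impact distance and the calibration factor
#' used to convert raw sensor units to m/s^2.
#'
#' @param recording_id character identifier
#' @param group species or treatment label
#' @param clutch_id clutch identifier
#' @param excitation_type one of \code{"pendulum_1cm"}, \code{"pendulum_2cm"},
#'   \code{"drop_large"}, \code{"drop_small"}, \code{"other"}
#' @param replicate integer replicate number within clutch and excitation type
#' @param distance_cm optional impact distance, cm
#' @param calibration raw-units per (m/s^2) scale factor (> 0); samples are
#'   divided by it on read
#' @param source_path optional path of the originating file
#' @param ... further fields kept verbatim (e.g. synthetic ground truth)
#' @return an object of class \code{recording_meta}
#' @export
recording_meta <- function(recording_id = NA_character_, group = NA_character_,
                           clutch_id = NA_character_,
                           excitation_type = "other", replicate = 1L,
                           distance_cm = NA_real_, calibration = 1,
                           source_path = NA_character_, ...) {
  excitation_type <- match.arg(excitation_type, EXCITATION_TYPES)
  if (!is.na(calibration) && (!is.numeric(calibration) || calibration <= 0)) {
    stop("`calibration` must be a positive scalar")
  }
  structure(
    c(list(recording_id = as.character(recording_id),
           group = as.character(group), clutch_id = as.character(clutch_id),
           excitation_type = excitation_type,
           replicate = as.integer(replicate),
           distance_cm = as.numeric(distance_cm),
           calibration = as.numeric(calibration),
           source_path = as.character(source_path)),
      list(...)),
    class = "recording_meta"
  )
}

#' Calibrated accelerometer recording
#'
#' A uniformly sampled acceleration trace in m/s^2 plus provenance metadata.
#'
#' @param samples numeric vector of acceleration values, m/s^2 (>= 2 finite
#'   values)
#' @param sample_rate_hz sampling rate, Hz (> 0)
#' @param meta a \code{\link{recording_meta}} object
#' @return an object of class \code{recording}
#' @export
recording <- function(samples, sample_rate_hz, meta = recording_meta()) {
  stopifnot(is.numeric(samples), length(samples) >= 2L,
            is.numeric(sample_rate_hz), length(sample_rate_hz) == 1L,
            sample_rate_hz > 0, inherits(meta, "recording_meta"))
  if (!all(is.finite(samples))) stop("recording samples must all be finite")
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.numeric(sample_rate_hz), meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate_hz
  cat(sprintf("Accelerometer recording '%s': %d samples @ %g Hz (%.4g s)\n",
              x$meta$recording_id, length(x$samples), x$sample_rate_hz, dur))
  cat(sprintf("  group %s, clutch %s, %s, replicate %d\n",
              x$meta$group, x$meta$clutch_id, x$meta$excitation_type,
              x$meta$replicate))
  cat(sprintf("  peak |a| = %.4g m/s^2\n", max(abs(x$samples))))
  invisible(x)
}

#' @export
plot.recording <- function(x, ...) {
  t <- (seq_along(x$samples) - 1L) / x$sample_rate_hz
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = expression(acceleration ~ (m/s^2)),
                 main = x$meta$recording_id, ...)
  invisible(x)
}

# Times (s) of each sample, t = 0 at the first sample.
recording_times <- function(x) (seq_along(x$samples) - 1L) / x$sample_rate_hz
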