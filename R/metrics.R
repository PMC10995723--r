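#' Peak amplitude of a recording
#'
#' Maximum absolute acceleration over the whole event (forced plus free
#' vibration) after removing the pre-event mean, so a DC offset in the
#' recording chain does not inflate the peak.
#'
#' @param rec a \code{\link{recording}}
#' @param pre_span optional \code{c(start_s, end_s)} of the pre-event
#'   baseline; defaults to the quiet leading segment when known, else the
#'   first 10\% of the trace
#' @return peak |a| in m/s^2
#' @export
peak_amplitude <- function(rec, pre_span = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$samples) == 0L) stop("empty recording")
  fs <- rec$sample_rate_hz
  if (is.null(pre_span)) {
    pre_span <- if (!is.null(rec$meta$pre_end_s) && rec$meta$pre_end_s > 0)
      c(0, rec$meta$pre_end_s) else c(0, 0.1 * length(rec$samples) / fs)
  }
  i0 <- max(1L, round(pre_span[1] * fs) + 1L)
  i1 <- min(length(rec$samples), max(i0, round(pre_span[2] * fs)))
  max(abs(rec$samples - mean(rec$samples[i0:i1])))
}

#' Total vibration duration above the noise floor
#'
#' Time between the first and last crossing of the smoothed amplitude
#' envelope above \code{threshold_factor} times the noise-floor RMS,
#' covering both the forced and the free portion of the event; 0 when the
#' envelope never exceeds the threshold.
#'
#' @param rec a \code{\link{recording}}
#' @param noise \code{noise_stats} from \code{\link{estimate_noise_floor}}
#' @param threshold_factor multiple of the noise RMS (default 3)
#' @return duration in seconds
#' @export
total_duration <- function(rec, noise, threshold_factor = 3) {
  stopifnot(inherits(rec, "recording"), inherits(noise, "noise_stats"),
            threshold_factor > 0)
  se <- smoothed_envelope(rec$samples, rec$sample_rate_hz)
  threshold <- threshold_factor * noise$rms
  if (threshold <= 0) threshold <- 1e-7 * max(se$env)
  above <- which(se$env > threshold)
  if (length(above) == 0L) return(0)
  (above[length(above)] - above[1L]) / rec$sample_rate_hz
}

#' Spatial attenuation of peak amplitude between impact distances
#'
#' Per-clutch change in mean peak amplitude between pendulum impacts 1 cm
#' and 2 cm from the sensor: the absolute change (2 cm mean minus 1 cm
#' mean), the proportional change (2 cm mean over 1 cm mean), and whether
#' the vibration was enhanced rather than attenuated with distance
#' (proportional change > 1).
#'
#' @param peaks_1cm,peaks_2cm numeric vectors of replicate peak amplitudes
#'   (m/s^2), nonempty
#' @param clutch_id identifier carried through to the result
#' @return object of class \code{attenuation_result}
#' @export
spatial_attenuation <- function(peaks_1cm, peaks_2cm, clutch_id = NA) {
  stopifnot(length(peaks_1cm) >= 1L, length(peaks_2cm) >= 1L)
  m1 <- mean(peaks_1cm); m2 <- mean(peaks_2cm)
  if (!(m1 > 0)) stop("mean peak at 1 cm is not positive; ratio undefined")
  structure(
    list(clutch_id = clutch_id, mean_peak_1cm = m1, mean_peak_2cm = m2,
         absolute_change = m2 - m1, proportional = m2 / m1,
         enhanced = m2 / m1 > 1),
    class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf(
    "Spatial attenuation, clutch %s: %.4g -> %.4g m/s^2 (1 -> 2 cm)\n",
    x$clutch_id, x$mean_peak_1cm, x$mean_peak_2cm))
  cat(sprintf("  absolute change %.4g m/s^2, proportional %.4g (%s)\n",
              x$absolute_change, x$proportional,
              if (x$enhanced) "enhanced with distance" else "attenuated"))
  invisible(x)
}
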