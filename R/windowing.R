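#' Estimate the recording noise floor
#'
#' Root-mean-square of a linearly detrended quiet span of the recording.
#'
#' @param rec a \code{\link{recording}}
#' @param quiet_span numeric \code{c(start_s, end_s)} within the recording;
#'   defaults to the pre-impact segment when the recording carries synthetic
#'   segment boundaries, otherwise the first 10\% of the trace
#' @return object of class \code{noise_stats} with fields \code{rms} (m/s^2)
#'   and \code{segment} (sample span used, 0-based half-open)
#' @export
estimate_noise_floor <- function(rec, quiet_span = NULL) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sample_rate_hz
  n <- length(rec$samples)
  if (is.null(quiet_span)) {
    quiet_span <- if (!is.null(rec$meta$pre_end_s) && rec$meta$pre_end_s > 0)
      c(0, rec$meta$pre_end_s) else c(0, 0.1 * n / fs)
  }
  stopifnot(length(quiet_span) == 2L, quiet_span[1] < quiet_span[2])
  i0 <- round(quiet_span[1] * fs)
  i1 <- round(quiet_span[2] * fs)
  if (i0 < 0 || i1 > n) stop("quiet span lies outside the recording")
  if ((i1 - i0) / fs < 0.01) {
    stop(sprintf("quiet span too short: %.4g s (need >= 10 ms)",
                 (i1 - i0) / fs))
  }
  x <- rec$samples[(i0 + 1L):i1]
  t <- seq_along(x)
  detr <- stats::lm.fit(cbind(1, t), x)$residuals
  structure(list(rms = sqrt(mean(detr^2)), segment = c(i0, i1)),
            class = "noise_stats")
}

#' Analysis window of a recording
#'
#' A half-open, 0-based span \code{[start_idx, end_idx)} of a recording's
#' samples, with times relative to the window start (t = 0 at the first
#' window sample; shifting the origin changes only the linear coefficients
#' and phase of the model, never omega or tau).
#'
#' @param rec a \code{\link{recording}}
#' @param start_idx,end_idx 0-based half-open sample span,
#'   \code{0 <= start_idx < end_idx <= length(rec$samples)}
#' @param detection_mode \code{"auto"} or \code{"manual"}
#' @return an object of class \code{vib_window}
#' @export
make_window <- function(rec, start_idx, end_idx, detection_mode = "auto") {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$samples)
  start_idx <- as.integer(start_idx); end_idx <- as.integer(end_idx)
  if (start_idx < 0L || start_idx >= end_idx || end_idx > n) {
    stop(sprintf("invalid window [%d, %d) for a %d-sample recording",
                 start_idx, end_idx, n))
  }
  samples <- rec$samples[(start_idx + 1L):end_idx]
  structure(
    list(recording_id = rec$meta$recording_id,
         start_idx = start_idx, end_idx = end_idx,
         sample_rate_hz = rec$sample_rate_hz,
         times = (seq_along(samples) - 1L) / rec$sample_rate_hz,
         samples = samples,
         n_zero_crossings = count_zero_crossings(samples),
         detection_mode = detection_mode),
    class = "vib_window"
  )
}

#' @export
print.vib_window <- function(x, ...) {
  cat(sprintf(
    "Analysis window of '%s': samples [%d, %d) @ %g Hz (%.4g s, %d zero crossings, %s)\n",
    x$recording_id, x$start_idx, x$end_idx, x$sample_rate_hz,
    (x$end_idx - x$start_idx) / x$sample_rate_hz, x$n_zero_crossings,
    x$detection_mode))
  invisible(x)
}

window_duration <- function(w) (w$end_idx - w$start_idx) / w$sample_rate_hz

#' Window from start/end times
#'
#' Convenience wrapper used for manual window overrides.
#'
#' @param rec a \code{\link{recording}}
#' @param start_s,end_s window bounds in seconds from the recording start
#' @return a \code{vib_window} with \code{detection_mode = "manual"}
#' @export
window_from_times <- function(rec, start_s, end_s) {
  make_window(rec, round(start_s * rec$sample_rate_hz),
              round(end_s * rec$sample_rate_hz), detection_mode = "manual")
}

# Smoothed Hilbert envelope plus the nominal period (in samples) used for
# smoothing; the coarse frequency comes from the post-maximum spectrum.
smoothed_envelope <- function(samples, sample_rate_hz) {
  i_max <- which.max(abs(samples))
  f_coarse <- dominant_frequency(samples[i_max:length(samples)],
                                 sample_rate_hz)
  if (!is.na(f_coarse) && f_coarse <= 0) f_coarse <- NA_real_
  period_n <- if (is.na(f_coarse)) max(3L, length(samples) %/% 20L)
              else max(3L, as.integer(round(sample_rate_hz / f_coarse)))
  env <- moving_average(analytic_envelope(samples), period_n)
  list(env = env, period_n = period_n, i_max = i_max, f_coarse = f_coarse)
}

#' Select the free-vibration window of a recording
#'
#' Automates the visual criterion used when sampling decaying sinusoids from
#' excitation-test waveforms: the window begins once the waveform has a
#' clear decaying form (first envelope peak after the global |a| maximum
#' from which the smoothed envelope is non-increasing over \code{k}
#' consecutive peaks, skipping the irregular impact transient) and ends when
#' the smoothed envelope falls below \code{threshold_factor} times the noise
#' floor, or at the recording end if it never does.
#'
#' @param rec a \code{\link{recording}}
#' @param noise a \code{noise_stats} from \code{\link{estimate_noise_floor}}
#'   on the same recording
#' @param k number of consecutive non-increasing envelope peaks required to
#'   call the decay "clear" (default 2)
#' @param threshold_factor multiple of the noise RMS defining
#'   indistinguishability from the noise floor (default 3)
#' @return a \code{vib_window}, or \code{NULL} when no decaying span exists
#'   (absence is a value, not an error)
#' @export
select_free_window <- function(rec, noise, k = 2L, threshold_factor = 3) {
  stopifnot(inherits(rec, "recording"), inherits(noise, "noise_stats"),
            k >= 1L, threshold_factor > 0)
  x <- rec$samples
  n <- length(x)
  se <- smoothed_envelope(x, rec$sample_rate_hz)
  env <- se$env
  threshold <- threshold_factor * noise$rms
  zero_floor <- threshold <= 0  # digitally silent background
  if (zero_floor) threshold <- 1e-7 * max(env)

  # a signal must exist at all
  if (max(env) < threshold || is.na(se$f_coarse)) return(NULL)

  # local maxima of |x| at least half a nominal period apart, after the peak
  half <- max(1L, se$period_n %/% 2L)
  ax <- abs(x)
  cand <- which(diff(sign(diff(ax))) < 0) + 1L
  cand <- cand[cand >= se$i_max]
  if (length(cand) == 0L) return(NULL)
  peaks <- cand[1L]
  for (p in cand[-1L]) if (p - peaks[length(peaks)] >= half) peaks <- c(peaks, p)

  # a clear sinusoid crosses its trend about twice per period; the
  # broadband impact transient crosses far more often and is skipped.
  # Crossings are counted with a hysteresis of twice the noise RMS so
  # noise jitter near the axis does not register.
  regular <- function(p) {
    span <- p:min(n, p + se$period_n)
    length(span) < 4L ||
      count_zero_crossings(x[span], tol = 2 * noise$rms) <= 6L
  }

  if (length(peaks) < k + 1L) return(NULL)
  start_idx <- NULL
  for (j in seq_len(length(peaks) - k)) {
    run <- env[peaks[j:(j + k)]]
    if (all(diff(run) <= 0) && regular(peaks[j])) {
      start_idx <- peaks[j] - 1L  # 0-based
      break
    }
  }
  if (is.null(start_idx)) return(NULL)

  if (zero_floor) {
    # the envelope never meets a zero noise floor; cap the window at the
    # support of the signal (last non-zero sample)
    live <- which(ax > 1e-9 * max(ax))
    end_idx <- live[length(live)]
  } else {
    below <- which(env < threshold)
    below <- below[below > start_idx + 1L]
    end_idx <- if (length(below)) below[1L] - 1L else n  # 0-based half-open
  }
  if (end_idx <= start_idx) return(NULL)

  # noise excursions produce spans shorter than one oscillation period or
  # spans whose envelope only grazes the threshold; both are absences
  if (end_idx - start_idx < max(8L, se$period_n)) return(NULL)
  if (!zero_floor && mean(env[(start_idx + 1L):end_idx]) < threshold) {
    return(NULL)
  }
  make_window(rec, start_idx, end_idx, detection_mode = "auto")
}

#' Validate an analysis window against the sampling criteria
#'
#' A usable window must span at least \code{min_cycles} full cycles of the
#' vibration (given a frequency hint) and show at least two zero crossings.
#'
#' @param window a \code{vib_window}
#' @param min_cycles minimum number of cycles (default 1)
#' @param f_hint frequency hint, Hz (> 0), e.g. from
#'   \code{\link{initial_estimates}} or ground truth
#' @return list with \code{pass} (logical) and \code{flags} (character
#'   vector naming each failed criterion: \code{"min_cycles"},
#'   \code{"zero_crossings"})
#' @export
validate_window <- function(window, min_cycles = 1, f_hint) {
  stopifnot(inherits(window, "vib_window"), is.numeric(f_hint), f_hint > 0)
  flags <- character(0)
  if (window_duration(window) < min_cycles / f_hint) {
    flags <- c(flags, "min_cycles")
  }
  if (window$n_zero_crossings < 2L) flags <- c(flags, "zero_crossings")
  list(pass = length(flags) == 0L, flags = flags)
}

#' Tabulate windows
#'
#' @param windows list of \code{vib_window} (NULLs are dropped)
#' @return data.frame with one row per window
#' @export
window_table <- function(windows) {
  windows <- Filter(Negate(is.null), windows)
  if (length(windows) == 0L) {
    return(data.frame(recording_id = character(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      n_zero_crossings = integer(0),
                      detection_mode = character(0)))
  }
  do.call(rbind, lapply(windows, function(w) {
    data.frame(recording_id = w$recording_id,
               start_s = w$start_idx / w$sample_rate_hz,
               end_s = w$end_idx / w$sample_rate_hz,
               duration_s = window_duration(w),
               n_zero_crossings = w$n_zero_crossings,
               detection_mode = w$detection_mode, stringsAsFactors = FALSE)
  }))
}
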