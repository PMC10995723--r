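# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# Centered moving average with window of `k` samples (k >= 1); edges use the
# available part of the window so the output has the same length as `x`.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L || length(x) < 2L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Count sign changes of a (linearly detrended) series; values within a
# relative tolerance of zero are skipped so flat or perfectly linear
# stretches do not register as crossings through rounding noise.
count_zero_crossings <- function(x, tol = NULL) {
  t <- seq_along(x)
  detr <- stats::lm.fit(cbind(1, t), x)$residuals
  if (is.null(tol) || tol <= 0) tol <- 1e-8 * max(abs(x), .Machine$double.xmin)
  s <- sign(detr)
  s <- s[abs(detr) > tol]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

# Magnitude of the analytic signal (Hilbert envelope), computed by zeroing
# the negative-frequency half of the spectrum.
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n %/% 2L + 1L] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# Deterministic 31-bit stream seed derived from a root seed and a label,
# so cohort recordings are reproducible independent of generation order.
derive_seed <- function(root, label) {
  stopifnot(length(root) == 1L, is.finite(root))
  acc <- as.double(root %% 2147483647)
  for (b in utf8ToInt(paste0("#", label))) {
    acc <- (acc * 131 + b) %% 2147483647
  }
  as.integer(acc)
}

# Frequency (Hz) of the dominant non-DC spectral peak of a detrended series.
dominant_frequency <- function(x, sample_rate_hz) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  t <- seq_len(n)
  detr <- stats::lm.fit(cbind(1, t), x)$residuals
  spec <- Mod(stats::fft(detr))[seq_len(n %/% 2L + 1L)]
  spec[1L] <- 0  # DC removed by detrending anyway
  k <- which.max(spec)
  if (spec[k] == 0) return(NA_real_)
  (k - 1L) * sample_rate_hz / n
}

stop_freevib <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "freevib_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
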