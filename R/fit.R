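# Core estimator: separable least squares for the linear coefficients
# nested inside Nelder-Mead minimization of the NRMSE over (omega, tau).

model_design <- function(omega, tau, times) {
  e <- exp(-times / tau)
  cbind(e * cos(omega * times), e * sin(omega * times), 1, times, times^2)
}

#' Least-squares solution of the linear coefficients
#'
#' For fixed angular frequency and time constant the model is linear in
#' A1-A5; this solves the 5-column least-squares problem over the window
#' samples exactly.
#'
#' @param omega angular frequency, rad/s (> 0)
#' @param tau time constant, s (> 0)
#' @param window a \code{vib_window} with >= 6 samples
#' @return list with \code{coeffs} (named a1..a5) and \code{residual}
#'   (sum of squared errors)
#' @export
solve_linear_coeffs <- function(omega, tau, window) {
  stopifnot(inherits(window, "vib_window"), omega > 0, tau > 0)
  if (length(window$samples) < 6L) stop("window must have at least 6 samples")
  X <- model_design(omega, tau, window$times)
  qr_X <- qr(X)
  d <- abs(diag(qr.R(qr_X)))
  rank <- sum(d > 1e-10 * max(d))
  if (rank < 5L) {
    stop(sprintf(
      "rank-deficient design (rank %d of 5): degenerate window times or parameters",
      rank))
  }
  beta <- qr.coef(qr_X, window$samples)
  r <- window$samples - X %*% beta
  list(coeffs = stats::setNames(as.numeric(beta),
                                c("a1", "a2", "a3", "a4", "a5")),
       residual = sum(r^2))
}

#' Root-mean-square error between observed and predicted series
#'
#' \deqn{\varepsilon = \sqrt{\tfrac{1}{N}\sum_{n=1}^{N} |a_n - \tilde a_n|^2}}
#' The fitter applies this to windows normalized to unit RMS, which makes
#' the conventional 0.5 acceptance threshold scale-invariant (see the
#' methods vignette).
#'
#' @param observed,predicted equal-length numeric vectors
#' @return epsilon (>= 0; 0 iff the vectors are identical)
#' @export
compute_nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop(sprintf("length mismatch: observed %d vs predicted %d",
                 length(observed), length(predicted)))
  }
  stopifnot(length(observed) >= 1L)
  sqrt(mean((observed - predicted)^2))
}

#' Initial frequency and time-constant estimates
#'
#' Automated surrogate for an initial visual read of the waveform:
#' the dominant spectral peak of the detrended window gives omega0 (falling
#' back to pi times the zero-crossing rate when the spectrum is
#' uninformative), and minus the inverse slope of a line fitted to the log
#' envelope peaks gives tau0 (falling back to the window duration when the
#' envelope does not decay).
#'
#' @param window a \code{vib_window} with >= 2 zero crossings
#' @return list with \code{omega0} (rad/s) and \code{tau0} (s)
#' @export
initial_estimates <- function(window) {
  stopifnot(inherits(window, "vib_window"))
  if (window$n_zero_crossings < 2L) {
    stop("window has fewer than 2 zero crossings; cannot estimate a frequency")
  }
  dur <- window_duration(window)
  f0 <- dominant_frequency(window$samples, window$sample_rate_hz)
  omega0 <- if (is.na(f0) || f0 <= 0) {
    pi * window$n_zero_crossings / dur
  } else {
    2 * pi * f0
  }

  # log-envelope regression over |x| peaks
  env <- analytic_envelope(window$samples - mean(window$samples))
  period_n <- max(3L, as.integer(round(2 * pi * window$sample_rate_hz /
                                         omega0)))
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  if (length(cand) >= 3L) {
    lp <- log(pmax(env[cand], .Machine$double.eps))
    slope <- stats::coef(stats::lm.fit(cbind(1, window$times[cand]),
                                       lp))[2L]
    tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else dur
  } else {
    tau0 <- dur
  }
  tau0 <- min(max(tau0, dur / 50), 50 * dur)  # keep the start sane
  list(omega0 = as.numeric(omega0), tau0 = as.numeric(tau0))
}

#' Fit the damped-sinusoid model to a window
#'
#' Minimizes the NRMSE over (omega, tau) with the linear coefficients A1-A5
#' solved exactly at every objective evaluation (variable projection). The
#' simplex operates on (log omega, log tau), which enforces positivity, and
#' is multi-started on a \{0.5, 1, 2\} x \{0.5, 1, 2\} grid around the
#' initial estimates; the best start is then polished by a simplex restart.
#' The window is normalized to unit RMS before fitting and \code{epsilon}
#' is reported on that scale; the returned coefficients are on the original
#' scale. The result is deterministic given the window and options.
#'
#' @param window a \code{vib_window} (should pass
#'   \code{\link{validate_window}})
#' @param start optional list with \code{omega0}, \code{tau0} overriding
#'   \code{\link{initial_estimates}}
#' @param start_factors multiplicative multi-start grid (default
#'   \code{c(0.5, 1, 2)} on each of omega and tau)
#' @param reltol relative convergence tolerance on epsilon (default 1e-10)
#' @param maxit maximum simplex iterations per start (default 2000)
#' @param max_samples objective evaluations run on an evenly decimated copy
#'   of the window capped at this many samples (default 2000; the decimated
#'   rate still oversamples any frequency the window can carry by a wide
#'   margin); the returned coefficients, epsilon and predicted series are
#'   recomputed on the full window
#' @return an object of class \code{modal_fit}: \code{params}
#'   (\code{\link{modal_params}}), \code{frequency_hz}, \code{period_s},
#'   \code{epsilon}, \code{epsilon_start}, \code{n_evals}, \code{converged},
#'   \code{window_duration_s}, \code{predicted}, \code{window}
#' @examples
#' spec <- synthetic_spec(frequency_hz = 25.65, tau_s = 0.10, noise_sd = 0,
#'                        impact_gain = 0, sample_rate_hz = 4000)
#' rec <- generate_recording(spec, seed = 1)
#' w <- window_from_times(rec, rec$meta$free_start_s, rec$meta$free_end_s)
#' fit <- fit_modal(w)
#' coef(fit)
#' @export
fit_modal <- function(window, start = NULL, start_factors = c(0.5, 1, 2),
                      reltol = 1e-10, maxit = 2000L, max_samples = 2000L) {
  stopifnot(inherits(window, "vib_window"), max_samples >= 6L)
  t <- window$times
  scale <- sqrt(mean(window$samples^2))
  if (scale <= 0) stop("window is identically zero; nothing to fit")
  y <- window$samples / scale
  n <- length(y)
  stride <- max(1L, as.integer(ceiling(n / max_samples)))
  keep <- seq.int(1L, n, by = stride)
  td <- t[keep]; yd <- y[keep]; td2 <- td^2
  nd <- length(yd)
  n_evals <- 0L

  objective <- function(par) {
    n_evals <<- n_evals + 1L
    omega <- exp(par[1L]); tau <- exp(par[2L])
    if (!is.finite(omega) || !is.finite(tau)) return(1e6)
    e <- exp(-td / tau)
    fit <- stats::.lm.fit(cbind(e * cos(omega * td), e * sin(omega * td),
                                1, td, td2), yd)
    sqrt(sum(fit$residuals^2) / nd)
  }

  # full-window epsilon at fixed (omega, tau), coefficients solved exactly
  full_eps <- function(omega, tau) {
    X <- model_design(omega, tau, t)
    beta <- qr.coef(qr(X), y)
    beta[is.na(beta)] <- 0
    compute_nrmse(y, as.numeric(X %*% beta))
  }

  init <- if (is.null(start)) initial_estimates(window) else start
  starts <- expand.grid(fo = start_factors, ft = start_factors)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(log(init$omega0 * starts$fo[i]), log(init$tau0 * starts$ft[i]))
    res <- tryCatch(
      stats::optim(par0, objective, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    res$eps0 <- full_eps(exp(par0[1L]), exp(par0[2L]))
    better <- is.null(best) || res$value < best$value - 1e-12 ||
      (abs(res$value - best$value) <= 1e-12 &&
         (exp(res$par[2L]) < exp(best$par[2L]) ||
            (exp(res$par[2L]) == exp(best$par[2L]) &&
               exp(res$par[1L]) < exp(best$par[1L]))))
    if (better) best <- res
  }

  if (is.null(best)) {
    return(structure(
      list(params = NULL, frequency_hz = NA_real_, period_s = NA_real_,
           epsilon = NA_real_, epsilon_start = NA_real_, n_evals = n_evals,
           converged = FALSE, window_duration_s = window_duration(window),
           predicted = rep(NA_real_, n), window = window, scale = scale),
      class = "modal_fit"))
  }

  # simplex restart from the optimum recovers precision a single collapsed
  # simplex can leave on the table; the convergence flag is the pre-polish
  # one (the restart often exits with the degenerate-simplex code at the
  # optimum itself)
  converged <- best$convergence == 0
  polish <- tryCatch(
    stats::optim(best$par, objective, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    polish$eps0 <- best$eps0
    best <- polish
  }

  omega <- exp(best$par[1L]); tau <- exp(best$par[2L])
  X <- model_design(omega, tau, t)
  beta <- as.numeric(qr.coef(qr(X), y))
  beta[is.na(beta)] <- 0
  predicted_norm <- as.numeric(X %*% beta)
  eps <- compute_nrmse(y, predicted_norm)
  params <- modal_params(omega = omega, tau = tau,
                         a1 = beta[1L] * scale, a2 = beta[2L] * scale,
                         a3 = beta[3L] * scale, a4 = beta[4L] * scale,
                         a5 = beta[5L] * scale)
  structure(
    list(params = params, frequency_hz = omega / (2 * pi),
         period_s = 2 * pi / omega, epsilon = eps,
         epsilon_start = best$eps0, n_evals = n_evals,
         converged = converged,
         window_duration_s = window_duration(window),
         predicted = predicted_norm * scale, window = window, scale = scale),
    class = "modal_fit")
}

#' @export
print.modal_fit <- function(x, digits = 4, ...) {
  cat("Damped-sinusoid model fit\n")
  if (is.null(x$params)) {
    cat("  (no converged solution)\n")
    return(invisible(x))
  }
  cat(sprintf("  frequency: %s Hz  (omega = %s rad/s, period %s s)\n",
              format(x$frequency_hz, digits = digits),
              format(x$params$omega, digits = digits),
              format(x$period_s, digits = digits)))
  cat(sprintf("  time constant tau: %s s\n",
              format(x$params$tau, digits = digits)))
  cat(sprintf("  NRMSE (unit-RMS scale): %s%s\n",
              format(x$epsilon, digits = digits),
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
summary.modal_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.modal_fit")
}

#' @export
print.summary.modal_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (!is.null(f$params)) {
    cat("  coefficients:\n")
    print(round(coef(f), digits = 6))
    cat(sprintf("  window: %.4g s, %d samples, %d objective evaluations\n",
                f$window_duration_s, length(f$window$samples), f$n_evals))
    cat(sprintf("  epsilon at best start: %s\n",
                format(f$epsilon_start, digits = digits)))
    cat(sprintf("  residual SD: %.4g m/s^2\n", stats::sd(residuals(f))))
  }
  invisible(x)
}

#' @export
coef.modal_fit <- function(object, ...) {
  if (is.null(object$params)) return(stats::setNames(rep(NA_real_, 7L),
    c("omega", "tau", "a1", "a2", "a3", "a4", "a5")))
  p <- object$params
  c(omega = p$omega, tau = p$tau, a1 = p$a1, a2 = p$a2, a3 = p$a3,
    a4 = p$a4, a5 = p$a5)
}

#' @export
fitted.modal_fit <- function(object, ...) object$predicted

#' @export
residuals.modal_fit <- function(object, ...) {
  object$window$samples - object$predicted
}

#' @export
predict.modal_fit <- function(object, times = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge; nothing to predict")
  if (is.null(times)) return(object$predicted)
  eval_model(object$params, times)
}

#' @export
plot.modal_fit <- function(x, ...) {
  w <- x$window
  graphics::plot(w$times, w$samples, type = "l", col = "grey40",
                 xlab = "time in window (s)",
                 ylab = expression(acceleration ~ (m/s^2)),
                 main = w$recording_id, ...)
  if (!is.null(x$params)) {
    graphics::lines(w$times, x$predicted, col = "red3", lwd = 1.5)
    env <- model_envelope(x$params, w$times) + x$params$a3 +
      x$params$a4 * w$times + x$params$a5 * w$times^2
    graphics::lines(w$times, env, col = "blue3", lty = 2)
    if (x$params$tau <= max(w$times)) {
      graphics::abline(v = x$params$tau, lty = 3)
    }
  }
  invisible(x)
}

#' @export
simulate.modal_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$params)) stop("fit did not converge; cannot simulate")
  if (!is.null(seed)) set.seed(seed)
  sd_r <- stats::sd(residuals(object))
  base <- eval_model(object$params, object$window$times)
  out <- replicate(nsim, base + stats::rnorm(length(base), sd = sd_r),
                   simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Tabulate modal fits
#'
#' Builds the flat fit table used by the filters and the pipeline, one row
#' per fit, joined with recording metadata when supplied.
#'
#' @param fits named list of \code{modal_fit} (names = recording ids)
#' @param meta optional data.frame with \code{recording_id}, \code{group},
#'   \code{excitation_type} columns to join
#' @return data.frame
#' @export
fit_table <- function(fits, meta = NULL) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    cf <- coef(f)
    data.frame(recording_id = id,
               start_s = f$window$start_idx / f$window$sample_rate_hz,
               end_s = f$window$end_idx / f$window$sample_rate_hz,
               window_duration_s = f$window_duration_s,
               frequency_hz = f$frequency_hz, tau_s = cf[["tau"]],
               omega = cf[["omega"]], a1 = cf[["a1"]], a2 = cf[["a2"]],
               a3 = cf[["a3"]], a4 = cf[["a4"]], a5 = cf[["a5"]],
               epsilon = f$epsilon, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(meta)) {
    keep <- intersect(c("recording_id", "group", "clutch_id",
                        "excitation_type", "replicate"), names(meta))
    tab <- merge(tab, unique(meta[keep]), by = "recording_id", sort = FALSE)
  }
  tab
}
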