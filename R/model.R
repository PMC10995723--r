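#' Damped-sinusoid model parameters
#'
#' Bundles the parameters of the single-mode free-vibration model
#' \deqn{a(t) = A_1 e^{-t/\tau}\cos(\omega t) + A_2 e^{-t/\tau}\sin(\omega t)
#'        + A_3 + A_4 t + A_5 t^2,}
#' i.e. an exponentially decaying sinusoid oscillating around a quadratic
#' trend. \code{omega} is the angular frequency in rad/s, \code{tau} the
#' exponential time constant in seconds (the time for the envelope to decay
#' to \eqn{e^{-1} \approx} 36.8\% of its starting value), \code{a1, a2} the
#' damped-component coefficients in m/s^2, and \code{a3, a4, a5} the trend
#' coefficients in m/s^2, m/s^3 and m/s^4.
#'
#' @param omega angular frequency, rad/s (> 0)
#' @param tau time constant, s (> 0)
#' @param a1,a2 damped cosine / sine coefficients, m/s^2
#' @param a3,a4,a5 quadratic-trend coefficients
#' @return an object of class \code{modal_params}
#' @examples
#' p <- modal_params(omega = 6, tau = 2, a1 = 1, a2 = 1)
#' eval_model(p, c(0, 2))
#' @export
modal_params <- function(omega, tau, a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0) {
  stopifnot(is.numeric(omega), length(omega) == 1L, is.finite(omega), omega > 0,
            is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  structure(
    list(omega = omega, tau = tau,
         a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5),
    class = "modal_params"
  )
}

#' @export
print.modal_params <- function(x, digits = 4, ...) {
  cat("Damped-sinusoid model parameters\n")
  cat(sprintf("  omega: %s rad/s  (f = %s Hz, T = %s s)\n",
              format(x$omega, digits = digits),
              format(x$omega / (2 * pi), digits = digits),
              format(2 * pi / x$omega, digits = digits)))
  cat(sprintf("  tau:   %s s\n", format(x$tau, digits = digits)))
  cat(sprintf("  damped coef (A1, A2): %s, %s m/s^2\n",
              format(x$a1, digits = digits), format(x$a2, digits = digits)))
  cat(sprintf("  trend coef (A3, A4, A5): %s, %s, %s\n",
              format(x$a3, digits = digits), format(x$a4, digits = digits),
              format(x$a5, digits = digits)))
  invisible(x)
}

#' Evaluate the free-vibration model
#'
#' Computes the model acceleration at the given times.
#'
#' @param params a \code{\link{modal_params}} object
#' @param times numeric vector of times, s (finite)
#' @return acceleration in m/s^2, same length as \code{times}
#' @export
eval_model <- function(params, times) {
  stopifnot(inherits(params, "modal_params"), is.numeric(times),
            all(is.finite(times)))
  e <- exp(-times / params$tau)
  params$a1 * e * cos(params$omega * times) +
    params$a2 * e * sin(params$omega * times) +
    params$a3 + params$a4 * times + params$a5 * times^2
}

#' Analytic amplitude envelope of the damped component
#'
#' The oscillatory part of the model has envelope
#' \eqn{\sqrt{A_1^2 + A_2^2}\, e^{-t/\tau}}; at \eqn{t = \tau} it has decayed
#' to \eqn{e^{-1} \approx} 36.8\% of its value at \eqn{t = 0}.
#'
#' @inheritParams eval_model
#' @return envelope amplitude, m/s^2
#' @export
model_envelope <- function(params, times) {
  stopifnot(inherits(params, "modal_params"), is.numeric(times),
            all(is.finite(times)))
  sqrt(params$a1^2 + params$a2^2) * exp(-times / params$tau)
}
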