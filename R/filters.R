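#' Fit-acceptance criteria
#'
#' The criteria under which a window's fitted parameters enter the analysis:
#' the NRMSE must be below \code{epsilon_max}, the fitted time constant must
#' be smaller than the window duration, frequency and time constant must be
#' positive, and both must lie within \code{z_max} standard deviations of
#' their grouping-cell mean (cells default to group x excitation type, and
#' the means/SDs are computed over the fits that survive the first three
#' criteria, in a single pass).
#'
#' @param epsilon_max NRMSE threshold (default 0.5)
#' @param require_tau_lt_window reject fits with tau >= window duration
#'   (default TRUE)
#' @param require_positive reject non-positive omega or tau (default TRUE)
#' @param z_max outlier threshold in SD units (default 3)
#' @param group_by character vector of fit-table columns defining the
#'   z-filter cells (default \code{c("group", "excitation_type")})
#' @return an object of class \code{fit_filter_criteria}
#' @export
fit_filter_criteria <- function(epsilon_max = 0.5,
                                require_tau_lt_window = TRUE,
                                require_positive = TRUE, z_max = 3,
                                group_by = c("group", "excitation_type")) {
  stopifnot(epsilon_max > 0, z_max > 0)
  structure(list(epsilon_max = epsilon_max,
                 require_tau_lt_window = require_tau_lt_window,
                 require_positive = require_positive, z_max = z_max,
                 group_by = group_by),
            class = "fit_filter_criteria")
}

#' Apply the fit-acceptance filters
#'
#' @param fits a fit table (see \code{\link{fit_table}}) with columns
#'   \code{epsilon}, \code{tau_s}, \code{frequency_hz}, \code{omega},
#'   \code{window_duration_s}, \code{converged}, plus the grouping columns
#' @param criteria a \code{\link{fit_filter_criteria}}
#' @return the table with added columns \code{accepted} (logical),
#'   \code{rejection_reasons} (";"-separated, "" when accepted) and
#'   \code{z_skipped} (TRUE where the z filter could not run because the
#'   grouping cell had a single survivor)
#' @export
apply_fit_filters <- function(fits, criteria = fit_filter_criteria()) {
  stopifnot(is.data.frame(fits), inherits(criteria, "fit_filter_criteria"))
  n <- nrow(fits)
  reasons <- vector("list", n)
  add <- function(i, r) reasons[[i]] <<- c(reasons[[i]], r)

  for (i in seq_len(n)) {
    if (!isTRUE(fits$converged[i]) || !is.finite(fits$epsilon[i])) {
      add(i, "not_converged")
      next
    }
    if (fits$epsilon[i] >= criteria$epsilon_max) add(i, "epsilon")
    if (criteria$require_tau_lt_window &&
        !(fits$tau_s[i] < fits$window_duration_s[i])) {
      add(i, "tau_vs_window")
    }
    if (criteria$require_positive &&
        !(fits$omega[i] > 0 && fits$tau_s[i] > 0)) {
      add(i, "not_positive")
    }
  }
  survive12 <- vapply(reasons, length, integer(1)) == 0L

  # single-pass z filter over the survivors of criteria i-ii
  z_skipped <- rep(FALSE, n)
  gb <- intersect(criteria$group_by, names(fits))
  cell <- if (length(gb)) interaction(fits[gb], drop = TRUE)
          else factor(rep("all", n))
  for (lv in levels(cell)) {
    idx <- which(cell == lv & survive12)
    if (length(idx) == 0L) next
    if (length(idx) == 1L) {
      z_skipped[idx] <- TRUE
      next
    }
    for (var in c("frequency_hz", "tau_s")) {
      m <- mean(fits[[var]][idx])
      s <- stats::sd(fits[[var]][idx])
      if (s == 0) next
      bad <- idx[abs(fits[[var]][idx] - m) / s > criteria$z_max]
      for (i in bad) add(i, paste0("z_", sub("_hz$|_s$", "", var)))
    }
  }

  fits$accepted <- vapply(reasons, length, integer(1)) == 0L
  fits$rejection_reasons <- vapply(reasons, paste, character(1),
                                   collapse = ";")
  fits$z_skipped <- z_skipped
  fits
}
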