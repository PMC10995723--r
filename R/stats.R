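#' Summarize a group of values
#'
#' Mean, sample SD (n - 1 denominator), range and count, the "mean +/- SD
#' (range)" convention of comparative tables.
#'
#' @param values numeric vector with >= 1 finite value
#' @param label optional group label
#' @return object of class \code{group_summary} with fields \code{n},
#'   \code{mean}, \code{sd}, \code{min}, \code{max}; for n = 1 the SD is 0
#'   by convention and \code{singleton} is set
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarize")
  n <- length(values)
  structure(
    list(label = label, n = n, mean = mean(values),
         sd = if (n > 1L) stats::sd(values) else 0,
         min = min(values), max = max(values), singleton = n == 1L),
    class = "group_summary")
}

#' Construct a group summary from printed statistics
#'
#' For recomputing two-sample tests from published mean/SD/n triples.
#'
#' @param n group size
#' @param mean,sd printed mean and SD
#' @param label optional group label
#' @return a \code{group_summary}
#' @export
group_summary <- function(n, mean, sd, label = NA_character_) {
  stopifnot(n >= 1L, sd >= 0)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd,
                 min = NA_real_, max = NA_real_, singleton = n == 1L),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 4, ...) {
  cat(sprintf("%s: n = %d, %s +/- %s (%s-%s)\n",
              if (is.na(x$label)) "group" else x$label, x$n,
              format(x$mean, digits = digits), format(x$sd, digits = digits),
              format(x$min, digits = digits), format(x$max, digits = digits)))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Closed-form Welch test from group summaries (so it can be run from
#' printed mean/SD/n triples as well as raw data):
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param x,y either two \code{group_summary} objects or two numeric
#'   vectors (vectors are summarized first)
#' @return object of class \code{welch_result} with \code{t}, \code{df},
#'   \code{p}
#' @examples
#' welch_t(group_summary(17, 40.12, 9.79), group_summary(16, 33.25, 7.97))
#' @export
welch_t <- function(x, y) {
  s1 <- if (inherits(x, "group_summary")) x else summarize_group(x)
  s2 <- if (inherits(y, "group_summary")) y else summarize_group(y)
  stopifnot(s1$n >= 2L, s2$n >= 2L)
  if (s1$sd == 0 && s2$sd == 0) {
    stop("both group SDs are zero; the Welch statistic is undefined")
  }
  v1 <- s1$sd^2 / s1$n
  v2 <- s2$sd^2 / s2$n
  se <- sqrt(v1 + v2)
  t_stat <- (s1$mean - s2$mean) / se
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1L) + v2^2 / (s2$n - 1L))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  structure(list(t = t_stat, df = df, p = p,
                 labels = c(s1$label, s2$label)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, digits = 4, ...) {
  cat(sprintf("Welch two-sample t-test%s: t = %s, df = %s, P = %s\n",
              if (all(is.na(x$labels))) "" else
                sprintf(" (%s vs %s)", x$labels[1], x$labels[2]),
              format(x$t, digits = digits), format(x$df, digits = digits),
              format(x$p, digits = digits)))
  invisible(x)
}

#' Score parameter recovery against ground truth
#'
#' Joins a fit table to a synthetic-cohort truth table on
#' \code{recording_id} and reports, per parameter (frequency and tau), the
#' bias (mean of estimate minus truth), the median relative error
#' |est - true| / true, and the RMSE, over accepted fits (or over all fits
#' when no \code{accepted} column is present).
#'
#' @param truth truth table from \code{\link{generate_cohort}}
#' @param fits fit table, optionally filtered (see
#'   \code{\link{apply_fit_filters}})
#' @return object of class \code{recovery_report}: a per-parameter
#'   data.frame plus join diagnostics
#' @export
recovery_metrics <- function(truth, fits) {
  stopifnot(is.data.frame(truth), is.data.frame(fits))
  if ("accepted" %in% names(fits)) fits <- fits[fits$accepted, , drop = FALSE]
  joined <- merge(truth, fits, by = "recording_id",
                  suffixes = c("_true", "_est"))
  if (nrow(joined) == 0L) stop("no recording_id overlap between truth and fits")
  score <- function(est, tru) {
    data.frame(bias = mean(est - tru),
               median_rel_err = stats::median(abs(est - tru) / tru),
               rmse = sqrt(mean((est - tru)^2)))
  }
  tab <- rbind(
    cbind(parameter = "frequency_hz",
          score(joined$frequency_hz, joined$true_frequency_hz)),
    cbind(parameter = "tau_s", score(joined$tau_s, joined$true_tau_s)))
  structure(
    list(metrics = tab, n_matched = nrow(joined),
         n_truth_unmatched = nrow(truth) - nrow(joined),
         n_fit_unmatched = nrow(fits) - nrow(joined), joined = joined),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d matched recordings", x$n_matched))
  if (x$n_truth_unmatched > 0L) {
    cat(sprintf(" (%d truth rows unmatched)", x$n_truth_unmatched))
  }
  cat("\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
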