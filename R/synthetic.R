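#' Specification of a synthetic excitation-test recording
#'
#' Describes one accelerometer-like trace: a leading quiet segment, a short
#' broadband impact transient, a single-mode exponentially decaying sinusoid
#' oscillating around a quadratic trend (the free vibration), and a trailing
#' quiet segment, with additive Gaussian noise throughout. The free segment
#' is evaluated with t = 0 at its first sample.
#'
#' @param frequency_hz free-vibration frequency, Hz (> 0; must satisfy
#'   \code{sample_rate_hz > 2 * frequency_hz})
#' @param tau_s exponential time constant of the amplitude decay, s (> 0)
#' @param amp_cos,amp_sin damped cosine / sine coefficients A1, A2, m/s^2
#' @param trend quadratic-trend coefficients \code{c(A3, A4, A5)}
#' @param sample_rate_hz sampling rate, Hz
#' @param pre_s,impact_s,free_s,post_s segment durations, s (all >= 0,
#'   \code{free_s > 0})
#' @param noise_sd additive Gaussian noise SD, m/s^2
#' @param impact_gain peak scale of the broadband impact transient, m/s^2;
#'   0 suppresses the transient
#' @return an object of class \code{synthetic_spec}
#' @seealso [generate_recording()], [noise_sd_for_snr()]
#' @export
synthetic_spec <- function(frequency_hz, tau_s, amp_cos = 1, amp_sin = 1,
                           trend = c(0, 0, 0), sample_rate_hz = 44100,
                           pre_s = 0.05, impact_s = 0.01, free_s = 0.15,
                           post_s = 0.05, noise_sd = 0, impact_gain = 5) {
  stopifnot(is.numeric(frequency_hz), frequency_hz > 0,
            is.numeric(tau_s), tau_s > 0, length(trend) == 3L,
            is.numeric(noise_sd), noise_sd >= 0, impact_gain >= 0)
  if (sample_rate_hz <= 2 * frequency_hz) {
    stop(sprintf(
      "Nyquist violation: sample_rate_hz (%g) must exceed 2 x frequency_hz (%g)",
      sample_rate_hz, 2 * frequency_hz))
  }
  if (any(c(pre_s, impact_s, free_s, post_s) < 0) || free_s <= 0) {
    stop("segment durations must be >= 0 and free_s > 0")
  }
  structure(
    list(frequency_hz = frequency_hz, tau_s = tau_s, amp_cos = amp_cos,
         amp_sin = amp_sin, trend = as.numeric(trend),
         sample_rate_hz = sample_rate_hz, pre_s = pre_s, impact_s = impact_s,
         free_s = free_s, post_s = post_s, noise_sd = noise_sd,
         impact_gain = impact_gain),
    class = "synthetic_spec"
  )
}

# Ground-truth model parameters implied by a synthetic spec.
spec_params <- function(spec) {
  modal_params(omega = 2 * pi * spec$frequency_hz, tau = spec$tau_s,
               a1 = spec$amp_cos, a2 = spec$amp_sin,
               a3 = spec$trend[1], a4 = spec$trend[2], a5 = spec$trend[3])
}

# Segment boundaries in samples: cumulative rounding keeps the total count
# equal to round(total duration x rate) exactly.
spec_boundaries <- function(spec) {
  round(cumsum(c(0, spec$pre_s, spec$impact_s, spec$free_s, spec$post_s)) *
          spec$sample_rate_hz)
}

#' Noise SD giving a target signal-to-noise ratio
#'
#' The SNR convention is RMS(noise-free free-vibration segment) / noise_sd;
#' the clean segment RMS is computed from the spec's model parameters, so
#' the result is deterministic.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @param snr target ratio (> 0)
#' @return noise SD in m/s^2
#' @export
noise_sd_for_snr <- function(spec, snr) {
  stopifnot(inherits(spec, "synthetic_spec"), snr > 0)
  b <- spec_boundaries(spec)
  n_free <- b[4] - b[3]
  t <- (seq_len(n_free) - 1L) / spec$sample_rate_hz
  clean <- eval_model(spec_params(spec), t)
  sqrt(mean(clean^2)) / snr
}

#' Generate a synthetic recording
#'
#' Realizes a \code{\link{synthetic_spec}} as a \code{\link{recording}}.
#' Generation is a pure function of \code{(spec, seed)}. The impact segment
#' is an exponentially decaying white Gaussian burst (time constant
#' \code{impact_s / 3}) scaled so its expected peak is about
#' \code{impact_gain}; it exists to exercise window detection, not to model
#' contact mechanics. Ground truth (model parameters, segment boundaries,
#' noise SD, seed) is stored in the recording metadata.
#'
#' @param spec a \code{\link{synthetic_spec}}
#' @param seed integer seed
#' @param meta optional \code{\link{recording_meta}}; ground-truth fields are
#'   added to it
#' @return a \code{\link{recording}}
#' @export
generate_recording <- function(spec, seed = 1L, meta = recording_meta()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  b <- spec_boundaries(spec)
  n_total <- b[5]
  fs <- spec$sample_rate_hz

  clean <- numeric(n_total)
  n_imp <- b[3] - b[2]
  n_free <- b[4] - b[3]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647))

  if (n_imp > 0L && spec$impact_gain > 0) {
    t_imp <- (seq_len(n_imp) - 1L) / fs
    burst <- stats::rnorm(n_imp) * exp(-t_imp / (spec$impact_s / 3))
    # ~2.5 SD covers the typical extreme of the early burst samples
    clean[(b[2] + 1L):b[3]] <- spec$impact_gain * burst / 2.5
  }

  t_free <- (seq_len(n_free) - 1L) / fs
  clean[(b[3] + 1L):b[4]] <- eval_model(spec_params(spec), t_free)

  noise <- if (spec$noise_sd > 0) stats::rnorm(n_total, sd = spec$noise_sd)
           else numeric(n_total)

  meta$spec <- spec
  meta$seed <- as.integer(seed)
  meta$pre_end_s <- b[2] / fs
  meta$free_start_s <- b[3] / fs
  meta$free_end_s <- b[4] / fs
  recording(clean + noise, fs, meta)
}

#' Group definition for a synthetic cohort
#'
#' Between-clutch variation is modelled by drawing each clutch's frequency
#' and time constant from normal distributions truncated at zero.
#'
#' @param label group (species) label
#' @param n_clutches number of clutches (>= 1)
#' @param frequency_hz_mean,frequency_hz_sd across-clutch distribution, Hz
#' @param tau_s_mean,tau_s_sd across-clutch distribution, s
#' @param excitation named list mapping excitation type to the free-vibration
#'   segment duration (s) it elicits
#' @param replicates_per_type recordings per clutch per excitation type
#' @return an object of class \code{cohort_group}
#' @export
cohort_group <- function(label, n_clutches, frequency_hz_mean, frequency_hz_sd,
                         tau_s_mean, tau_s_sd,
                         excitation = list(pendulum_1cm = 0.1,
                                           pendulum_2cm = 0.1,
                                           drop_large = 0.1,
                                           drop_small = 0.1),
                         replicates_per_type = 5L) {
  stopifnot(n_clutches >= 1L, replicates_per_type >= 1L,
            frequency_hz_sd >= 0, tau_s_sd >= 0,
            frequency_hz_mean > 0, tau_s_mean > 0,
            length(excitation) >= 1L, !is.null(names(excitation)))
  stopifnot(all(names(excitation) %in% EXCITATION_TYPES))
  structure(
    list(label = label, n_clutches = as.integer(n_clutches),
         frequency_hz_mean = frequency_hz_mean,
         frequency_hz_sd = frequency_hz_sd,
         tau_s_mean = tau_s_mean, tau_s_sd = tau_s_sd,
         excitation = excitation,
         replicates_per_type = as.integer(replicates_per_type)),
    class = "cohort_group"
  )
}

#' Species presets for the two-treefrog comparison
#'
#' Cohort-group presets emulating published excitation-test results for two
#' sympatric \emph{Agalychnis} treefrogs: \emph{A. spurrelli} clutches
#' vibrate at roughly 105 Hz with a ~0.02 s decay time constant, and
#' \emph{A. callidryas} at roughly 26 Hz with a ~0.10 s time constant.
#' Free-segment durations per excitation type follow the published mean
#' analysis-window lengths.
#'
#' @param species \code{"spurrelli"} or \code{"callidryas"}
#' @param n_clutches clutches per group (defaults: 16 and 17 respectively)
#' @return a \code{\link{cohort_group}}
#' @export
species_preset <- function(species = c("spurrelli", "callidryas"),
                           n_clutches = NULL) {
  species <- match.arg(species)
  if (species == "spurrelli") {
    cohort_group(
      label = "A_spurrelli", n_clutches = n_clutches %||% 16L,
      frequency_hz_mean = 105.15, frequency_hz_sd = 36.7,
      tau_s_mean = 0.02, tau_s_sd = 0.02,
      excitation = list(pendulum_1cm = 0.036, pendulum_2cm = 0.028,
                        drop_large = 0.018, drop_small = 0.017))
  } else {
    cohort_group(
      label = "A_callidryas", n_clutches = n_clutches %||% 17L,
      frequency_hz_mean = 25.65, frequency_hz_sd = 26.06,
      tau_s_mean = 0.10, tau_s_sd = 0.06,
      excitation = list(pendulum_1cm = 0.137, pendulum_2cm = 0.160,
                        drop_large = 0.147, drop_small = 0.160))
  }
}

#' Synthetic cohort specification
#'
#' @param groups list of \code{\link{cohort_group}} objects
#' @param seed root integer seed; every per-recording stream is derived from
#'   it deterministically, so generation is order-independent
#' @param snr signal-to-noise ratio applied to every recording
#'   (RMS(clean free segment) / noise SD); \code{Inf} for noise-free
#' @param sample_rate_hz sampling rate for all recordings, Hz
#' @param impact_gain impact-transient peak scale, m/s^2
#' @return an object of class \code{cohort_spec}
#' @export
cohort_spec <- function(groups, seed = 1L, snr = 10, sample_rate_hz = 44100,
                        impact_gain = 5) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "cohort_group")),
            snr > 0)
  structure(
    list(groups = groups, seed = as.integer(seed), snr = snr,
         sample_rate_hz = sample_rate_hz, impact_gain = impact_gain),
    class = "cohort_spec"
  )
}

# One truncated-normal draw (> 0); sd = 0 returns the mean.
rtrunc_pos <- function(mean, sd, what, label, max_retries = 100L) {
  if (sd == 0) {
    if (mean <= 0) stop(sprintf("non-positive %s for group %s", what, label))
    return(mean)
  }
  for (i in seq_len(max_retries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > 0) return(x)
  }
  stop(sprintf(
    "could not draw a positive %s for group '%s' after %d retries",
    what, label, max_retries))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-clutch (frequency, tau) pairs from each group's truncated-normal
#' distribution, then generates \code{replicates_per_type} recordings per
#' excitation type per clutch. Each recording's oscillation phase and a mild
#' quadratic trend are randomized; noise SD is set per recording from the
#' cohort SNR. The returned truth table has one row per recording with all
#' generating parameters.
#'
#' @param cohort a \code{\link{cohort_spec}}
#' @return list with \code{recordings} (list of \code{\link{recording}}) and
#'   \code{truth} (data.frame)
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  recordings <- list()
  rows <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  for (g in cohort$groups) {
    for (ci in seq_len(g$n_clutches)) {
      clutch_id <- sprintf("%s_c%02d", g$label, ci)
      set.seed(derive_seed(cohort$seed, paste0("clutch/", clutch_id)))
      f_true <- rtrunc_pos(g$frequency_hz_mean, g$frequency_hz_sd,
                           "frequency", g$label)
      tau_true <- rtrunc_pos(g$tau_s_mean, g$tau_s_sd, "tau", g$label)
      for (ex in names(g$excitation)) {
        for (rep_i in seq_len(g$replicates_per_type)) {
          rec_id <- sprintf("%s_%s_r%d", clutch_id, ex, rep_i)
          rec_seed <- derive_seed(cohort$seed, paste0("rec/", rec_id))
          set.seed(rec_seed)
          phase <- stats::runif(1L, 0, 2 * pi)
          trend <- c(stats::rnorm(1L, 0, 0.05), stats::rnorm(1L, 0, 0.5),
                     stats::rnorm(1L, 0, 2))
          spec <- synthetic_spec(
            frequency_hz = f_true, tau_s = tau_true,
            amp_cos = cos(phase), amp_sin = sin(phase), trend = trend,
            sample_rate_hz = cohort$sample_rate_hz,
            free_s = g$excitation[[ex]],
            impact_gain = cohort$impact_gain)
          spec$noise_sd <- if (is.finite(cohort$snr))
            noise_sd_for_snr(spec, cohort$snr) else 0
          meta <- recording_meta(recording_id = rec_id, group = g$label,
                                 clutch_id = clutch_id, excitation_type = ex,
                                 replicate = rep_i,
                                 distance_cm = switch(ex, pendulum_1cm = 1,
                                                      pendulum_2cm = 2,
                                                      NA_real_))
          rec <- generate_recording(spec, seed = rec_seed, meta = meta)
          recordings[[rec_id]] <- rec
          rows[[rec_id]] <- data.frame(
            recording_id = rec_id, group = g$label, clutch_id = clutch_id,
            excitation_type = ex, replicate = rep_i,
            true_frequency_hz = f_true, true_tau_s = tau_true,
            a1 = spec$amp_cos, a2 = spec$amp_sin, a3 = trend[1],
            a4 = trend[2], a5 = trend[3], noise_sd = spec$noise_sd,
            seed = rec_seed,
            free_start_s = rec$meta$free_start_s,
            free_end_s = rec$meta$free_end_s,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(recordings = recordings, truth = truth)
}
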