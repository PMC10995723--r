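#' Pipeline configuration
#'
#' Bundles every knob of the simulate - window - fit - filter - metrics -
#' stats pipeline. Exactly one of \code{cohort} (simulate) or
#' \code{manifest} (read WAV files listed in a manifest CSV) must be given.
#'
#' @param out_dir output directory (created if needed)
#' @param cohort optional \code{\link{cohort_spec}} to simulate
#' @param manifest optional path to a manifest CSV with columns
#'   \code{recording_id, group, clutch_id, excitation_type, replicate,
#'   calibration, wav_path}
#' @param seed integer root seed (overrides the cohort's seed)
#' @param threshold_factor,k,min_cycles windowing options (see
#'   \code{\link{select_free_window}}, \code{\link{validate_window}})
#' @param overrides optional path to a manual-window CSV with columns
#'   \code{recording_id, start_s, end_s}; listed recordings bypass automatic
#'   detection
#' @param criteria a \code{\link{fit_filter_criteria}}
#' @param write_wav also write the simulated recordings as WAV + sidecars
#' @param use_truth_windows take windows from the simulated truth
#'   boundaries instead of automatic detection (recovery studies)
#' @return an object of class \code{pipeline_config}
#' @export
pipeline_config <- function(out_dir, cohort = NULL, manifest = NULL,
                            seed = 1L, threshold_factor = 3, k = 2L,
                            min_cycles = 1, overrides = NULL,
                            criteria = fit_filter_criteria(),
                            write_wav = FALSE, use_truth_windows = FALSE) {
  cfg <- structure(
    list(out_dir = out_dir, cohort = cohort, manifest = manifest,
         seed = as.integer(seed), threshold_factor = threshold_factor,
         k = as.integer(k), min_cycles = min_cycles, overrides = overrides,
         criteria = criteria, write_wav = isTRUE(write_wav),
         use_truth_windows = isTRUE(use_truth_windows)),
    class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$cohort) == is.null(cfg$manifest)) {
    problems <- c(problems, "exactly one of `cohort` or `manifest` required")
  }
  if (!is.null(cfg$cohort) && !inherits(cfg$cohort, "cohort_spec")) {
    problems <- c(problems, "`cohort` must be a cohort_spec")
  }
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest)) {
    problems <- c(problems, sprintf("manifest not found: %s", cfg$manifest))
  }
  if (!is.numeric(cfg$threshold_factor) || cfg$threshold_factor <= 0) {
    problems <- c(problems, "`threshold_factor` must be positive")
  }
  if (!is.numeric(cfg$min_cycles) || cfg$min_cycles <= 0) {
    problems <- c(problems, "`min_cycles` must be positive")
  }
  if (length(problems)) {
    stop_freevib(paste0("invalid pipeline config:\n  - ",
                        paste(problems, collapse = "\n  - ")),
                 "freevib_config_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Schema (all keys except \code{out_dir} optional):
#' \preformatted{
#' out_dir: results/
#' seed: 1
#' cohort:
#'   preset: two_species     # or a list of group definitions under `groups`
#'   snr: 10
#'   sample_rate_hz: 44100
#' manifest: path/to/manifest.csv
#' windowing: {threshold_factor: 3, k: 2, min_cycles: 1, overrides: path.csv}
#' filters: {epsilon_max: 0.5, z_max: 3}
#' write_wav: false
#' use_truth_windows: false
#' }
#' Group definitions under \code{cohort.groups} take the arguments of
#' \code{\link{cohort_group}}.
#'
#' @param path YAML file path
#' @return a \code{\link{pipeline_config}}
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_freevib(sprintf("config file not found: %s", path),
                 "freevib_config_error")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) {
    stop_freevib("config must set `out_dir`", "freevib_config_error")
  }
  seed <- y$seed %||% 1L
  cohort <- NULL
  if (!is.null(y$cohort)) {
    groups <- if (identical(y$cohort$preset, "two_species")) {
      list(species_preset("spurrelli"), species_preset("callidryas"))
    } else if (!is.null(y$cohort$groups)) {
      lapply(y$cohort$groups, function(g) do.call(cohort_group, g))
    } else {
      stop_freevib("cohort needs `preset: two_species` or `groups`",
                   "freevib_config_error")
    }
    cohort <- cohort_spec(groups, seed = seed, snr = y$cohort$snr %||% 10,
                          sample_rate_hz = y$cohort$sample_rate_hz %||% 44100,
                          impact_gain = y$cohort$impact_gain %||% 5)
  }
  w <- y$windowing %||% list()
  f <- y$filters %||% list()
  pipeline_config(
    out_dir = y$out_dir, cohort = cohort, manifest = y$manifest, seed = seed,
    threshold_factor = w$threshold_factor %||% 3, k = w$k %||% 2L,
    min_cycles = w$min_cycles %||% 1, overrides = w$overrides,
    criteria = fit_filter_criteria(
      epsilon_max = f$epsilon_max %||% 0.5,
      require_tau_lt_window = f$require_tau_lt_window %||% TRUE,
      require_positive = f$require_positive %||% TRUE,
      z_max = f$z_max %||% 3),
    write_wav = y$write_wav %||% FALSE,
    use_truth_windows = y$use_truth_windows %||% FALSE)
}

load_manifest_recordings <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("recording_id", "wav_path")
  if (!all(need %in% names(man))) {
    stop_freevib(sprintf("manifest must have columns %s",
                         paste(need, collapse = ", ")),
                 "freevib_config_error")
  }
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$wav_path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    meta <- recording_meta(
      recording_id = man$recording_id[i],
      group = man$group[i] %||% NA_character_,
      clutch_id = man$clutch_id[i] %||% NA_character_,
      excitation_type = man$excitation_type[i] %||% "other",
      replicate = man$replicate[i] %||% 1L,
      distance_cm = man$distance_cm[i] %||% NA_real_,
      calibration = man$calibration[i] %||% 1)
    read_recording(p, meta)
  })
  names(recs) <- man$recording_id
  recs
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) recordings, selects free-vibration windows, fits
#' the damped-sinusoid model, applies the acceptance filters, computes
#' waveform metrics and group statistics, scores parameter recovery when
#' ground truth exists, and writes every table as CSV plus a JSON run
#' manifest with the seed and the counts at each stage. Identical config
#' and seed give byte-identical CSV outputs.
#'
#' @param config a \code{\link{pipeline_config}}
#' @return (invisibly) a list with all tables and the manifest
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    cohort$seed <- config$seed
    sim <- generate_cohort(cohort)
    recordings <- sim$recordings
    truth <- sim$truth
    utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE)
    if (config$write_wav) {
      write_cohort(recordings, file.path(config$out_dir, "recordings"))
    }
  } else {
    recordings <- load_manifest_recordings(config$manifest)
  }

  overrides <- if (!is.null(config$overrides)) {
    utils::read.csv(config$overrides, stringsAsFactors = FALSE)
  }

  windows <- list()
  meta_rows <- list()
  for (id in names(recordings)) {
    rec <- recordings[[id]]
    m <- rec$meta
    meta_rows[[id]] <- data.frame(
      recording_id = id, group = m$group, clutch_id = m$clutch_id,
      excitation_type = m$excitation_type, replicate = m$replicate,
      stringsAsFactors = FALSE)
    w <- NULL
    if (!is.null(overrides) && id %in% overrides$recording_id) {
      o <- overrides[overrides$recording_id == id, ][1L, ]
      w <- tryCatch(window_from_times(rec, o$start_s, o$end_s),
                    error = function(e) NULL)
    } else if (config$use_truth_windows && !is.null(m$free_start_s)) {
      w <- window_from_times(rec, m$free_start_s, m$free_end_s)
      w$detection_mode <- "truth"
    } else {
      noise <- tryCatch(estimate_noise_floor(rec), error = function(e) NULL)
      if (!is.null(noise)) {
        w <- select_free_window(rec, noise, k = config$k,
                                threshold_factor = config$threshold_factor)
      }
    }
    windows[[id]] <- w
  }
  meta_tab <- do.call(rbind, meta_rows)
  win_tab <- window_table(windows)
  utils::write.csv(win_tab, file.path(config$out_dir, "windows.csv"),
                   row.names = FALSE)
  windows <- Filter(Negate(is.null), windows)

  fits <- list()
  n_invalid <- 0L
  for (id in names(windows)) {
    w <- windows[[id]]
    f <- tryCatch(fit_modal(w), error = function(e) NULL)
    if (is.null(f)) { n_invalid <- n_invalid + 1L; next }
    v <- validate_window(w, min_cycles = config$min_cycles,
                         f_hint = max(f$frequency_hz, 1e-9))
    if (!v$pass) { n_invalid <- n_invalid + 1L; next }
    fits[[id]] <- f
  }

  counts <- c(recordings = length(recordings), windows = length(windows),
              fits = length(fits), accepted = 0L)
  if (length(fits) == 0L) {
    stop_freevib("no window produced a valid model fit",
                 "freevib_empty_fits", counts = counts)
  }

  ftab <- fit_table(fits, meta = meta_tab)
  ftab <- apply_fit_filters(ftab, config$criteria)
  counts["accepted"] <- sum(ftab$accepted)
  utils::write.csv(ftab, file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE)
  if (counts["accepted"] == 0L) {
    stop_freevib(
      sprintf("all %d fits were rejected by the acceptance filters (%s)",
              nrow(ftab),
              paste(unique(unlist(strsplit(ftab$rejection_reasons, ";"))),
                    collapse = ", ")),
      "freevib_empty_fits", counts = counts)
  }

  # waveform metrics per recording
  met <- do.call(rbind, lapply(names(recordings), function(id) {
    rec <- recordings[[id]]
    noise <- tryCatch(estimate_noise_floor(rec), error = function(e) NULL)
    data.frame(
      recording_id = id,
      peak_amplitude = peak_amplitude(rec),
      total_duration_s = if (is.null(noise)) NA_real_ else
        total_duration(rec, noise, config$threshold_factor),
      stringsAsFactors = FALSE)
  }))
  met <- merge(meta_tab, met, by = "recording_id", sort = TRUE)
  utils::write.csv(met, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)

  att <- attenuation_table(recordings)
  if (!is.null(att)) {
    utils::write.csv(att, file.path(config$out_dir, "attenuation.csv"),
                     row.names = FALSE)
  }

  stats_tab <- group_stats_table(ftab[ftab$accepted, , drop = FALSE], met)
  utils::write.csv(stats_tab, file.path(config$out_dir, "stats.csv"),
                   row.names = FALSE)

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- recovery_metrics(truth, ftab)
    utils::write.csv(recovery$metrics,
                     file.path(config$out_dir, "recovery.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    counts = as.list(counts),
    rejection_reasons = table_to_list(ftab$rejection_reasons))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(windows = win_tab, fits = ftab, metrics = met,
                 attenuation = att, stats = stats_tab, recovery = recovery,
                 truth = truth, manifest = manifest))
}

table_to_list <- function(reasons) {
  reasons <- unlist(strsplit(reasons[reasons != ""], ";"))
  if (length(reasons) == 0L) return(list())
  as.list(table(reasons))
}

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  # a stable content fingerprint without extra dependencies
  s <- jsonlite::toJSON(rapply(unclass(cfg), unclass, how = "replace"),
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 997)) %% 2147483647
}

# Per-clutch 1 cm vs 2 cm attenuation over pendulum impacts, when both
# distances are present.
attenuation_table <- function(recordings) {
  peaks <- lapply(recordings, function(rec) {
    data.frame(clutch_id = rec$meta$clutch_id, group = rec$meta$group,
               excitation_type = rec$meta$excitation_type,
               peak = peak_amplitude(rec), stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, peaks)
  out <- list()
  for (cl in unique(peaks$clutch_id)) {
    p1 <- peaks$peak[peaks$clutch_id == cl &
                       peaks$excitation_type == "pendulum_1cm"]
    p2 <- peaks$peak[peaks$clutch_id == cl &
                       peaks$excitation_type == "pendulum_2cm"]
    if (length(p1) == 0L || length(p2) == 0L) next
    a <- spatial_attenuation(p1, p2, clutch_id = cl)
    out[[cl]] <- data.frame(
      clutch_id = cl, group = peaks$group[peaks$clutch_id == cl][1L],
      mean_peak_1cm = a$mean_peak_1cm, mean_peak_2cm = a$mean_peak_2cm,
      absolute_change = a$absolute_change, proportional = a$proportional,
      enhanced = a$enhanced, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

# Group summaries plus Welch comparisons (first two groups) for the fitted
# parameters and waveform metrics.
group_stats_table <- function(accepted, metrics) {
  vars <- list(frequency_hz = accepted, tau_s = accepted,
               epsilon = accepted, window_duration_s = accepted,
               peak_amplitude = metrics, total_duration_s = metrics)
  groups <- sort(unique(stats::na.omit(c(accepted$group, metrics$group))))
  rows <- list()
  for (v in names(vars)) {
    tab <- vars[[v]]
    if (!"group" %in% names(tab)) next
    sums <- lapply(groups, function(g) {
      vals <- tab[[v]][tab$group == g & is.finite(tab[[v]])]
      if (length(vals)) summarize_group(vals, label = g) else NULL
    })
    names(sums) <- groups
    sums <- Filter(Negate(is.null), sums)
    wt <- if (length(sums) >= 2L && sums[[1]]$n >= 2L && sums[[2]]$n >= 2L &&
              (sums[[1]]$sd > 0 || sums[[2]]$sd > 0)) {
      welch_t(sums[[1]], sums[[2]])
    }
    for (s in sums) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = s$label, n = s$n, mean = s$mean, sd = s$sd,
        min = s$min, max = s$max,
        t = if (is.null(wt)) NA_real_ else wt$t,
        df = if (is.null(wt)) NA_real_ else wt$df,
        p = if (is.null(wt)) NA_real_ else wt$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
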