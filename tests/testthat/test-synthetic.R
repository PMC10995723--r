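test_that("noise-free generation equals the model evaluation bitwise", {
  spec <- synthetic_spec(frequency_hz = 40, tau_s = 0.05, trend = c(0, 0, 0),
                         sample_rate_hz = 4000, noise_sd = 0, impact_gain = 0)
  rec <- generate_recording(spec, seed = 3)
  fs <- spec$sample_rate_hz
  i0 <- round(rec$meta$free_start_s * fs)
  i1 <- round(rec$meta$free_end_s * fs)
  free <- rec$samples[(i0 + 1):i1]
  t <- (seq_along(free) - 1) / fs
  expect_identical(free, eval_model(modal_params(2 * pi * 40, 0.05,
                                                 a1 = spec$amp_cos,
                                                 a2 = spec$amp_sin), t))
  # quiet segments are exactly zero without noise
  expect_identical(rec$samples[seq_len(i0 - round(spec$impact_s * fs))],
                   rep(0, i0 - round(spec$impact_s * fs)))
})

test_that("generation is a pure function of (spec, seed)", {
  spec <- synthetic_spec(frequency_hz = 40, tau_s = 0.05, noise_sd = 0.02,
                         sample_rate_hz = 4000)
  r1 <- generate_recording(spec, seed = 11)
  r2 <- generate_recording(spec, seed = 11)
  r3 <- generate_recording(spec, seed = 12)
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("sample count equals round(total duration x rate) exactly", {
  for (fs in c(1000, 44100)) {
    spec <- synthetic_spec(frequency_hz = 30, tau_s = 0.1,
                           sample_rate_hz = fs, pre_s = 0.0503,
                           impact_s = 0.0117, free_s = 0.1531,
                           post_s = 0.0499)
    rec <- generate_recording(spec, seed = 1)
    total <- spec$pre_s + spec$impact_s + spec$free_s + spec$post_s
    expect_identical(length(rec$samples), as.integer(round(total * fs)))
  }
})

test_that("the SNR convention holds empirically (Monte Carlo)", {
  spec <- synthetic_spec(frequency_hz = 25.65, tau_s = 0.10,
                         sample_rate_hz = 4000, free_s = 0.44,
                         impact_gain = 0)
  spec$noise_sd <- noise_sd_for_snr(spec, 10)
  fs <- spec$sample_rate_hz
  ratios <- vapply(1:100, function(s) {
    rec <- generate_recording(spec, seed = s)
    i0 <- round(rec$meta$free_start_s * fs); i1 <- round(rec$meta$free_end_s * fs)
    free <- rec$samples[(i0 + 1):i1]
    t <- (seq_along(free) - 1) / fs
    clean <- eval_model(modal_params(2 * pi * 25.65, 0.10, spec$amp_cos,
                                     spec$amp_sin), t)
    rms(free - clean) / rms(clean)
  }, numeric(1))
  expect_equal(mean(ratios), 1 / 10, tolerance = 0.1)
})

test_that("invalid specs are rejected with descriptive errors", {
  expect_error(synthetic_spec(frequency_hz = 600, tau_s = 0.1,
                              sample_rate_hz = 1000), "Nyquist")
  expect_error(synthetic_spec(frequency_hz = 10, tau_s = 0.1, pre_s = -1),
               "duration")
  expect_error(synthetic_spec(frequency_hz = 10, tau_s = -0.1))
})

test_that("zero-SD cohorts reproduce the group means exactly", {
  sim <- generate_cohort(mini_cohort(seed = 5))
  expect_true(all(sim$truth$true_frequency_hz == 50))
  expect_true(all(sim$truth$true_tau_s == 0.03))
})

test_that("the two-species preset cohort has 660 recordings and truth rows", {
  cohort <- cohort_spec(list(species_preset("spurrelli"),
                             species_preset("callidryas")),
                        seed = 1, snr = 10, sample_rate_hz = 2000)
  sim <- generate_cohort(cohort)
  # 16 x 4 x 5 + 17 x 4 x 5
  expect_identical(length(sim$recordings), 660L)
  expect_identical(nrow(sim$truth), 660L)
  counts <- table(sim$truth$group)
  expect_identical(as.integer(counts[["A_spurrelli"]]), 320L)
  expect_identical(as.integer(counts[["A_callidryas"]]), 340L)
})

test_that("cohort generation is deterministic under the root seed", {
  cohort <- mini_cohort(seed = 9, snr = 10)
  s1 <- generate_cohort(cohort)
  s2 <- generate_cohort(cohort)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$recordings[[1]]$samples, s2$recordings[[1]]$samples)
})
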