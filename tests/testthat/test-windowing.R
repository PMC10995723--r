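test_that("noise floor: zero span gives rms 0, Gaussian span recovers its SD", {
  quiet <- recording(rep(0, 2000), 1000, recording_meta())
  expect_identical(estimate_noise_floor(quiet, c(0, 1))$rms, 0)

  set.seed(4)
  noisy <- recording(rnorm(1000, sd = 0.01), 1000, recording_meta())
  expect_equal(estimate_noise_floor(noisy, c(0, 1))$rms, 0.01,
               tolerance = 0.05)
})

test_that("noise floor rejects short or out-of-range spans", {
  rec <- make_noise_recording(n = 1000, sample_rate_hz = 1000)
  expect_error(estimate_noise_floor(rec, c(0, 0.005)), "too short")
  expect_error(estimate_noise_floor(rec, c(0.5, 2)), "outside")
})

test_that("window selection brackets the free segment on synthetic data", {
  spec <- synthetic_spec(frequency_hz = 25, tau_s = 0.1,
                         sample_rate_hz = 44100, free_s = 0.4,
                         impact_gain = 5)
  spec$noise_sd <- noise_sd_for_snr(spec, 20)
  for (s in 1:5) {
    rec <- generate_recording(spec, seed = s)
    noise <- estimate_noise_floor(rec)
    w <- select_free_window(rec, noise)
    expect_false(is.null(w))
    start_s <- w$start_idx / 44100
    end_s <- w$end_idx / 44100
    # start within 1.5 cycles after the true free-segment start
    expect_gte(start_s, rec$meta$free_start_s - 1 / 25)
    expect_lte(start_s, rec$meta$free_start_s + 1.5 / 25)
    # end within 20% of the analytic envelope crossing tau ln(A0 / threshold)
    t_cross <- 0.1 * log(sqrt(2) / (3 * noise$rms))
    expect_lt(abs((end_s - rec$meta$free_start_s) - t_cross), 0.2 * t_cross)
  }
})

test_that("pure-noise recordings yield no window", {
  rec <- make_noise_recording(n = 4000, sd = 0.01, sample_rate_hz = 4000,
                              seed = 8)
  noise <- estimate_noise_floor(rec, c(0, 1))
  expect_null(select_free_window(rec, noise))
})

test_that("noise-free recordings end the window near the free-segment end", {
  spec <- synthetic_spec(frequency_hz = 50, tau_s = 0.08,
                         sample_rate_hz = 8000, free_s = 0.3, noise_sd = 0,
                         impact_gain = 5)
  rec <- generate_recording(spec, seed = 2)
  noise <- estimate_noise_floor(rec)
  expect_identical(noise$rms, 0)
  w <- select_free_window(rec, noise)
  expect_false(is.null(w))
  # envelope never reaches a zero noise floor; capped at the segment end
  expect_lt(abs(w$end_idx / 8000 - rec$meta$free_end_s), 0.002)
})

test_that("lowering threshold_factor never shortens the window", {
  spec <- synthetic_spec(frequency_hz = 30, tau_s = 0.08,
                         sample_rate_hz = 8000, free_s = 0.3,
                         impact_gain = 5)
  spec$noise_sd <- noise_sd_for_snr(spec, 15)
  for (s in 1:10) {
    rec <- generate_recording(spec, seed = s)
    noise <- estimate_noise_floor(rec)
    w3 <- select_free_window(rec, noise, threshold_factor = 3)
    w2 <- select_free_window(rec, noise, threshold_factor = 2)
    if (is.null(w3) || is.null(w2)) next
    expect_gte(w2$end_idx - w2$start_idx, w3$end_idx - w3$start_idx)
  }
})

test_that("windows avoid the first half of the impact segment at SNR >= 10", {
  spec <- synthetic_spec(frequency_hz = 40, tau_s = 0.08,
                         sample_rate_hz = 8000, free_s = 0.3,
                         impact_s = 0.02, impact_gain = 5)
  spec$noise_sd <- noise_sd_for_snr(spec, 10)
  hits <- 0L; found <- 0L
  for (s in 1:100) {
    rec <- generate_recording(spec, seed = s)
    w <- select_free_window(rec, estimate_noise_floor(rec))
    if (is.null(w)) next
    found <- found + 1L
    impact_mid <- (rec$meta$pre_end_s + spec$impact_s / 2) * 8000
    if (w$start_idx < impact_mid) hits <- hits + 1L
  }
  expect_gte(found, 95L)
  expect_lte(hits / found, 0.05)
})

test_that("validate_window applies the cycle and crossing criteria", {
  w <- make_truth_window(100, 0.05, sample_rate_hz = 4000, free_s = 0.04)
  v <- validate_window(w, min_cycles = 1, f_hint = 100)  # 4 cycles
  expect_true(v$pass)

  w_short <- make_truth_window(100, 0.05, sample_rate_hz = 4000,
                               free_s = 0.005)
  v2 <- validate_window(w_short, min_cycles = 1, f_hint = 100)
  expect_false(v2$pass)
  expect_true("min_cycles" %in% v2$flags)

  # a constant trace never crosses its trend
  w_flat <- make_window(recording(rep(0.5, 100), 1000, recording_meta()),
                        0, 100)
  v3 <- validate_window(w_flat, min_cycles = 0.01, f_hint = 10)
  expect_true("zero_crossings" %in% v3$flags)
})

test_that("window indexing is 0-based half-open and bounds-checked", {
  rec <- make_noise_recording(n = 100)
  w <- make_window(rec, 0, 100)
  expect_identical(length(w$samples), 100L)
  expect_identical(w$times[1], 0)
  expect_error(make_window(rec, -1, 50))
  expect_error(make_window(rec, 10, 10))
  expect_error(make_window(rec, 0, 101))
})
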