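test_that("peak amplitude is the max |a| after pre-event baseline removal", {
  rec <- recording(c(0, 1, -3, 2), 1000, recording_meta())
  expect_identical(peak_amplitude(rec, pre_span = c(0, 0.001)), 3)

  # a DC offset does not inflate the peak
  rec_dc <- recording(c(0, 1, -3, 2) + 10, 1000, recording_meta())
  expect_identical(peak_amplitude(rec_dc, pre_span = c(0, 0.001)), 3)
})

test_that("peak amplitude sits in the impact segment when the impact dominates", {
  spec <- synthetic_spec(frequency_hz = 40, tau_s = 0.08,
                         sample_rate_hz = 8000, free_s = 0.2,
                         impact_gain = 5)
  spec$noise_sd <- noise_sd_for_snr(spec, 20)
  rec <- generate_recording(spec, seed = 6)
  pk <- peak_amplitude(rec)
  i_pk <- which.max(abs(rec$samples - mean(rec$samples[1:100])))
  expect_gt(pk, 2)  # impact-scale, not free-vibration scale (~1.4)
  expect_lte(i_pk / 8000, rec$meta$free_start_s + 0.005)
})

test_that("an all-zero recording has zero peak", {
  rec <- recording(rep(0, 100), 1000, recording_meta())
  expect_identical(peak_amplitude(rec, pre_span = c(0, 0.05)), 0)
})

test_that("peak amplitude is invariant under sign flip", {
  rec <- make_noise_recording(n = 500, seed = 12)
  flipped <- recording(-rec$samples, rec$sample_rate_hz, rec$meta)
  expect_equal(peak_amplitude(rec, pre_span = c(0, 0.05)),
               peak_amplitude(flipped, pre_span = c(0, 0.05)))
})

test_that("total duration matches the closed-form envelope crossing", {
  spec <- synthetic_spec(frequency_hz = 50, tau_s = 0.1, amp_cos = 1,
                         amp_sin = 0, sample_rate_hz = 8000, pre_s = 0.02,
                         impact_s = 0, free_s = 0.5, post_s = 0.02,
                         noise_sd = 0, impact_gain = 0)
  rec <- generate_recording(spec, seed = 1)
  noise <- structure(list(rms = 0.05 / 3, segment = c(0, 160)),
                     class = "noise_stats")
  d <- total_duration(rec, noise, threshold_factor = 3)
  expect_equal(d, 0.1 * log(1 / 0.05), tolerance = (1 / 50) / (0.1 * log(20)))
})

test_that("pure noise has zero duration above its own floor", {
  rec <- make_noise_recording(n = 4000, sd = 0.01, sample_rate_hz = 4000,
                              seed = 5)
  noise <- estimate_noise_floor(rec, c(0, 1))
  expect_lte(total_duration(rec, noise, threshold_factor = 4), 0.01)
})

test_that("total duration is non-increasing in the threshold factor", {
  spec <- synthetic_spec(frequency_hz = 40, tau_s = 0.08,
                         sample_rate_hz = 8000, free_s = 0.3,
                         impact_gain = 5)
  spec$noise_sd <- noise_sd_for_snr(spec, 15)
  rec <- generate_recording(spec, seed = 9)
  noise <- estimate_noise_floor(rec)
  ds <- vapply(c(2, 3, 5, 8), function(k) total_duration(rec, noise, k),
               numeric(1))
  expect_true(all(diff(ds) <= 0))
})

test_that("spatial attenuation reports absolute and proportional change", {
  a <- spatial_attenuation(c(2, 2, 2, 2, 2), c(1, 1, 1, 1, 1), "c1")
  expect_equal(a$absolute_change, -1)
  expect_equal(a$proportional, 0.5)
  expect_false(a$enhanced)

  b <- spatial_attenuation(1.0, 1.2, "c2")
  expect_equal(b$proportional, 1.2)
  expect_true(b$enhanced)

  d <- spatial_attenuation(rep(1, 5), rep(2, 5), "c3")
  expect_equal(d$proportional, 2.0)

  # absolute change and proportional - 1 share sign
  for (m2 in c(0.3, 1, 1.7)) {
    r <- spatial_attenuation(rep(1, 3), rep(m2, 3))
    expect_equal(sign(r$absolute_change), sign(r$proportional - 1))
  }
  expect_error(spatial_attenuation(c(0, 0), c(1, 1)), "not positive")
})
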