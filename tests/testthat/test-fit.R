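test_that("linear coefficients are recovered exactly at the true (omega, tau)", {
  p <- modal_params(omega = 2 * pi * 30, tau = 0.07, a1 = 0.8, a2 = -0.4,
                    a3 = 0.1, a4 = 0.5, a5 = 2)
  w <- make_truth_window(30, 0.07, amp_cos = 0.8, amp_sin = -0.4,
                         trend = c(0.1, 0.5, 2), sample_rate_hz = 4000,
                         free_s = 0.2)
  sol <- solve_linear_coeffs(p$omega, p$tau, w)
  expect_equal(unname(sol$coeffs), c(0.8, -0.4, 0.1, 0.5, 2),
               tolerance = 1e-9)
  expect_lt(sol$residual, 1e-18)
})

test_that("a constant window is explained by a3 alone", {
  rec <- recording(rep(2.5, 200), 1000, recording_meta())
  w <- make_window(rec, 0, 200)
  sol <- solve_linear_coeffs(2 * pi * 20, 0.05, w)
  expect_equal(sol$coeffs[["a3"]], 2.5, tolerance = 1e-8)
  expect_equal(unname(sol$coeffs[c("a1", "a2", "a4", "a5")]), rep(0, 4),
               tolerance = 1e-8)
  expect_lt(sol$residual, 1e-16)
})

test_that("least-squares coefficients are unbiased under noise", {
  set.seed(7)
  p <- modal_params(omega = 2 * pi * 25, tau = 0.1, a1 = 1, a2 = 0.5)
  n_mc <- 400
  a1_hat <- numeric(n_mc)
  sigma <- 0.1
  base <- make_truth_window(25, 0.1, amp_cos = 1, amp_sin = 0.5,
                            sample_rate_hz = 2000, free_s = 0.2)
  clean <- base$samples
  for (i in seq_len(n_mc)) {
    w <- base
    w$samples <- clean + rnorm(length(clean), sd = sigma)
    a1_hat[i] <- solve_linear_coeffs(p$omega, p$tau, w)$coeffs[["a1"]]
  }
  # mean within 3 standard errors of the truth
  expect_lt(abs(mean(a1_hat) - 1), 3 * sd(a1_hat) / sqrt(n_mc))
})

test_that("a degenerate design is rejected with a named defect", {
  rec <- recording(sin(seq(0, 10, length.out = 200)), 1000, recording_meta())
  w <- make_window(rec, 0, 200)
  # omega ~ 0 makes the sine column collinear with t and cosine with 1
  expect_error(solve_linear_coeffs(1e-10, 0.05, w), "rank-deficient")
  expect_error(solve_linear_coeffs(2 * pi, 0.05,
                                   make_window(rec, 0, 5)), "6 samples")
})

test_that("compute_nrmse matches the printed formula", {
  expect_identical(compute_nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_nrmse(c(1, 0, -1, 0), c(0, 0, 0, 0)), sqrt(2 / 4),
               tolerance = 1e-12)
  # mean-based: duplicating both vectors leaves epsilon unchanged
  o <- c(0.3, -1, 2); p <- c(0.1, -0.4, 1.6)
  expect_equal(compute_nrmse(rep(o, 2), rep(p, 2)), compute_nrmse(o, p))
  expect_error(compute_nrmse(1:3, 1:4), "length mismatch")
})

test_that("initial estimates land near the truth on clean windows", {
  w <- make_truth_window(25, 0.1, sample_rate_hz = 4000, free_s = 0.15)
  est <- initial_estimates(w)
  expect_equal(est$omega0, 2 * pi * 25, tolerance = 0.2)
  expect_equal(est$tau0, 0.1, tolerance = 0.5)
})

test_that("an undamped sinusoid yields tau0 at least the window duration", {
  rec <- recording(sin(2 * pi * 20 * seq(0, 0.5, by = 1e-3)), 1000,
                   recording_meta())
  w <- make_window(rec, 0, length(rec$samples))
  est <- initial_estimates(w)
  expect_gte(est$tau0, (w$end_idx - w$start_idx) / 1000 * 0.99)
})

test_that("initial estimates refuse windows without two zero crossings", {
  rec <- recording(seq(0, 1, length.out = 100), 1000, recording_meta())
  w <- make_window(rec, 0, 100)
  expect_error(initial_estimates(w), "zero crossings")
})

test_that("fit_modal recovers all parameters on noise-free windows", {
  w <- make_truth_window(25.65, 0.10, amp_cos = 0.9, amp_sin = -0.6,
                         trend = c(0.2, 1, -3), sample_rate_hz = 4000,
                         free_s = 0.3)
  fit <- fit_modal(w)
  expect_true(fit$converged)
  expect_equal(fit$frequency_hz, 25.65, tolerance = 1e-4)
  cf <- coef(fit)
  expect_equal(cf[["tau"]], 0.10, tolerance = 1e-4)
  expect_equal(unname(cf[c("a1", "a2", "a3", "a4", "a5")]),
               c(0.9, -0.6, 0.2, 1, -3), tolerance = 1e-4)
  expect_lt(fit$epsilon, 1e-8)
  # diagnostics invariants
  expect_lte(fit$epsilon, fit$epsilon_start + 1e-10)
  expect_equal(fit$frequency_hz * fit$period_s, 1, tolerance = 1e-12)
})

test_that("median recovered frequency stays within 5% at SNR 10 on short windows", {
  spec <- synthetic_spec(frequency_hz = 105.15, tau_s = 0.02,
                         sample_rate_hz = 8000, free_s = 0.03,
                         impact_gain = 0)
  spec$noise_sd <- noise_sd_for_snr(spec, 10)
  fr <- vapply(1:60, function(s) {
    rec <- generate_recording(spec, seed = s)
    w <- window_from_times(rec, rec$meta$free_start_s, rec$meta$free_end_s)
    fit_modal(w)$frequency_hz
  }, numeric(1))
  expect_lt(abs(median(fr) - 105.15) / 105.15, 0.05)
})

test_that("fitted parameters are always positive and methods are coherent", {
  w <- make_truth_window(40, 0.05, sample_rate_hz = 4000, free_s = 0.1,
                         noise_sd = 0.2, seed = 21)
  fit <- fit_modal(w)
  cf <- coef(fit)
  expect_gt(cf[["omega"]], 0)
  expect_gt(cf[["tau"]], 0)
  expect_equal(fitted(fit) + residuals(fit), w$samples, tolerance = 1e-12)
  expect_identical(predict(fit), fitted(fit))
  expect_equal(predict(fit, 0), cf[["a1"]] + cf[["a3"]], tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(length(sims), 2L)
  expect_identical(length(sims[[1]]), length(w$samples))
})
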