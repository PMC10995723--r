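# Shared fixtures, all generated in code.

rms <- function(x) sqrt(mean(x^2))

# Noise-free free-vibration window generated straight from known parameters.
make_truth_window <- function(frequency_hz, tau_s, amp_cos = 1, amp_sin = 1,
                              trend = c(0, 0, 0), sample_rate_hz = 4000,
                              free_s = 0.2, noise_sd = 0, seed = 1) {
  spec <- synthetic_spec(frequency_hz = frequency_hz, tau_s = tau_s,
                         amp_cos = amp_cos, amp_sin = amp_sin, trend = trend,
                         sample_rate_hz = sample_rate_hz, free_s = free_s,
                         noise_sd = noise_sd, impact_gain = 0)
  rec <- generate_recording(spec, seed = seed)
  window_from_times(rec, rec$meta$free_start_s, rec$meta$free_end_s)
}

# A pure-noise recording with no deterministic signal.
make_noise_recording <- function(n = 1000, sd = 0.01, sample_rate_hz = 4000,
                                 seed = 1) {
  set.seed(seed)
  recording(rnorm(n, sd = sd), sample_rate_hz,
            recording_meta(recording_id = paste0("noise_", seed)))
}

# Minimal two-group noise-free cohort for pipeline tests.
mini_cohort <- function(seed = 1, snr = Inf) {
  g1 <- cohort_group("g1", n_clutches = 2L, frequency_hz_mean = 50,
                     frequency_hz_sd = 0, tau_s_mean = 0.03, tau_s_sd = 0,
                     excitation = list(pendulum_1cm = 0.2),
                     replicates_per_type = 2L)
  cohort_spec(list(g1), seed = seed, snr = snr, sample_rate_hz = 4000)
}
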