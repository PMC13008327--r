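test_that("degenerate parameters give a flat series at baseline", {
  p <- sim_params(n_patients = 1, band_amplitude_mean = rep(0, 5),
                  white_noise_sd = 0, drift_amplitude = 0,
                  spike_rate_per_h = 0, gap_rate_per_h_start = 0,
                  gap_rate_per_h_end = 0, dropout_scale = 1e9,
                  pp_noise_sd = 0, seed = 2)
  sim <- simulate_cohort(p)
  s <- sim$records[[1]]$series[["continuous.MBP"]]
  expect_true(all(s$valid))
  expect_equal(diff(range(s$values)), 0)
  expect_equal(s$values[1], sim$truth$baseline_mbp[1])
  # the MBP identity holds exactly between simulated channels
  r <- sim$records[[1]]
  expect_equal(r$series[["continuous.MBP"]]$values,
               derive_mbp(r$series[["continuous.SBP"]]$values,
                          r$series[["continuous.DBP"]]$values),
               tolerance = 1e-10)
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  p <- sim_params(n_patients = 4, seed = 77)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$truth, b$truth)
  for (id in names(a$records)) {
    for (key in names(a$records[[id]]$series)) {
      expect_identical(a$records[[id]]$series[[key]]$values,
                       b$records[[id]]$series[[key]]$values)
    }
  }
  # truth is invariant to whether series are generated
  c0 <- simulate_cohort(p, include_series = FALSE)
  expect_identical(c0$truth, a$truth)
})

test_that("the cuff schedule subsamples the truth with independent noise", {
  sim <- simulate_cohort(sim_params(n_patients = 1, cuff_missing_prob = 0,
                                    seed = 12))
  int <- sim$records[[1]]$series[["intermittent.SBP"]]
  expect_equal(int$times, intermittent_schedule())
  expect_length(int$times, 36)
})

test_that("zero effect size gives the configured prevalence", {
  p <- sim_params(n_patients = 2000, effect_log_or_per_sd = 0, seed = 5)
  sim <- simulate_cohort(p, include_series = FALSE)
  rate <- mean(vapply(sim$records, function(r) r$ht_outcome, TRUE))
  se <- sqrt(0.29 * 0.71 / 2000)
  expect_lt(abs(rate - 0.29), 3 * se)
  # and the event probability itself is exactly calibrated
  expect_equal(mean(sim$truth$p_ht), 0.29, tolerance = 1e-8)
})

test_that("a strong short-band effect separates measured energies by outcome", {
  wins <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    p <- sim_params(n_patients = 60, effect_log_or_per_sd = 1.5,
                    seed = 500 + r)
    sim <- simulate_cohort(p)
    recs <- lapply(sim$records, preprocess_record)
    elig <- eligibility_report(recs, "P1")
    ft <- build_feature_table(recs, "P1", eligibility = elig)
    oc <- outcome_covariates(recs, ft)
    if (length(unique(oc$outcome)) < 2) next
    short_cols <- sprintf("cont_MBP_wav_%s_mmHg2_per_min",
                          c("1_2", "2_4", "4_8", "8_16"))
    e <- rowSums(ft[, short_cols])
    wins <- wins + (mean(e[oc$outcome == 1], na.rm = TRUE) >
                      mean(e[oc$outcome == 0], na.rm = TRUE))
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("generated band energy is recovered by the wavelet estimator", {
  # amplitude 5 in the 8-16-min band: closed-form energy 12.5 mmHg^2/min
  meas <- c()
  for (sd0 in 1:50) {
    p <- sim_params(n_patients = 1, band_amplitude_mean = c(0, 0, 5, 0, 0),
                    band_amplitude_sdlog = 0, seed = sd0)
    sim <- simulate_cohort(p)
    s <- suppressWarnings(
      preprocess_record(sim$records[[1]]))$series[["continuous.MBP"]]
    span <- longest_contiguous_window(s, analysis_window("P1"))
    if (is.null(span)) next
    we <- wavelet_band_energies(
      s, span, wavelet_config(band_convention = "finest-2-4min"))
    meas <- c(meas, we$band_energy[["wav_8_16"]])
  }
  expect_gt(length(meas), 40)
  expect_lt(abs(mean(meas) / 12.5 - 1), 0.20)
})

test_that("the sub-32-min energy sum is an unbiased target at defaults", {
  # target = closed-form oscillation energy + white-noise share sigma^2 2^-j
  rel <- c()
  for (sd0 in 1:40) {
    p <- sim_params(n_patients = 1, seed = 900 + sd0)
    sim <- simulate_cohort(p)
    s <- suppressWarnings(
      preprocess_record(sim$records[[1]]))$series[["continuous.MBP"]]
    span <- longest_contiguous_window(s, analysis_window("P1"))
    if (is.null(span)) next
    we <- wavelet_band_energies(
      s, span, wavelet_config(band_convention = "finest-2-4min"))
    meas <- sum(we$band_energy[1:4])
    tgt <- sum(sim$truth[1, sprintf("energy_band%d", 1:4)]) +
      p$white_noise_sd^2 * sum(2^-(1:4))
    rel <- c(rel, meas / tgt)
  }
  expect_gt(length(rel), 30)
  expect_lt(abs(mean(rel) - 1), 0.10)
})

test_that("injected artefact spikes are flagged by QC on noise-free fixtures", {
  found <- 0; injected <- 0; false_flags <- 0; valid_n <- 0
  for (sd0 in 1:10) {
    p <- sim_params(n_patients = 1, white_noise_sd = 0, spike_rate_per_h = 2,
                    gap_rate_per_h_start = 0, gap_rate_per_h_end = 0,
                    dropout_scale = 1e9, pp_noise_sd = 0, seed = 40 + sd0)
    sim <- simulate_cohort(p)
    cont <- simulate_continuous(p, list(
      baseline_mbp = sim$truth$baseline_mbp[1],
      pp = sim$truth$pulse_pressure[1],
      band_amp = unlist(sim$truth[1, sprintf("amp_band%d", 1:5)])),
      seed = bpvar:::patient_seed(p$seed, 1))
    s <- remove_artifacts(average_to_minute(cont$series$MBP))
    spikes <- cont$spike_minutes
    injected <- injected + length(spikes)
    found <- found + sum(!s$valid[spikes + 1])
    false_flags <- false_flags + sum(!s$valid[setdiff(0:1439, spikes) + 1])
    valid_n <- valid_n + 1440 - length(spikes)
  }
  expect_gte(found / injected, 0.90)       # nearly every spike caught
  expect_lt(false_flags / valid_n, 0.01)   # almost no collateral masking
})
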