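# Synthetic post-thrombectomy cohort generator.
#
# Band-limited oscillations are random-phase sinusoid mixtures, so every
# patient's true per-band oscillation energy is known in closed form
# (amplitude^2 / 2 per band, mmHg^2/min) and serves as an exact oracle for
# the wavelet band-energy estimator. The haemorrhagic-transformation outcome
# depends on the latent (pre-noise, pre-missingness) sub-32-min oscillation
# energy, preserving a clean estimand for odds-ratio recovery tests.

#' Simulation parameters
#'
#' Defaults emulate the structure of a 24-h post-thrombectomy monitoring
#' cohort: lognormal baseline MBP around 100 mmHg, slow circadian-scale
#' drift, five dyadic oscillation bands (physical periods 2-4 to 32-64 min at
#' 1-min sampling), device noise and artefact spikes on the continuous
#' channel, a missingness hazard that grows as finger-cuff tolerance wears
#' off plus a device-dropout time, a noisy arm-cuff sampled on the
#' 15/30/60-min schedule, covariate margins matching the published cohort,
#' and a logistic outcome with 29% prevalence whose log-odds rise by
#' `effect_log_or_per_sd` per SD of latent sub-32-min band energy.
#'
#' @param n_patients Cohort size.
#' @param ht_prevalence Marginal outcome prevalence (default 0.29).
#' @param baseline_mbp_meanlog,baseline_mbp_sdlog Lognormal baseline MBP.
#' @param pulse_pressure_mean,pulse_pressure_sdlog Lognormal per-patient
#'   pulse pressure (SBP - DBP); SBP = MBP + 2/3 PP, DBP = MBP - 1/3 PP so
#'   the MBP identity holds exactly.
#' @param pp_noise_sd Within-patient minute-to-minute pulse-pressure
#'   fluctuation, mmHg.
#' @param drift_amplitude Peak-to-peak slow drift over 24 h, mmHg.
#' @param band_amplitude_mean Mean oscillation amplitude per band (finest
#'   first), mmHg.
#' @param band_amplitude_sdlog Between-patient lognormal spread of band
#'   amplitudes.
#' @param n_sin_per_band Sinusoids per band (random frequency within the
#'   band, random phase; each carries an equal share of the band's power).
#' @param white_noise_sd Continuous-device measurement noise after 1-min
#'   averaging, mmHg.
#' @param spike_rate_per_h,spike_magnitude Artefact spikes on the continuous
#'   channels: Poisson rate and central absolute magnitude, mmHg.
#' @param gap_rate_per_h_start,gap_rate_per_h_end Linearly increasing hazard
#'   of gap onsets over the 24 h (wear-off).
#' @param gap_duration_meanlog,gap_duration_sdlog Lognormal gap durations,
#'   minutes (median 4 min: most gaps imputable, some not).
#' @param dropout_shape,dropout_scale Weibull device-dropout time, minutes;
#'   recording is lost from the dropout time onward.
#' @param cuff_noise_sd Arm-cuff reading noise, mmHg.
#' @param cuff_missing_prob Per-slot probability that a scheduled cuff
#'   reading is missing.
#' @param nihss_probs,ivt_prob,antithrombotic_prob,ttr_shape,ttr_rate
#'   Covariate margins (NIHSS category probabilities; Bernoulli IV
#'   thrombolysis and periprocedural antithrombotic; gamma time to
#'   reperfusion in hours).
#' @param effect_log_or_per_sd Log odds of HT per 1 SD of latent sub-32-min
#'   band energy (0 = null cohort; default log(2.23) ~ 0.8).
#' @param effect_bands Indices of the bands (1 = finest) whose latent energy
#'   drives the outcome; default 1:4, i.e. physical periods below 32 min.
#' @param prob_missing_outcome,prob_missing_covariate Probability a patient
#'   lacks the outcome label / one covariate (default 0).
#' @param seed Global seed; per-patient substreams are derived from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 200L,
                       ht_prevalence = 0.29,
                       baseline_mbp_meanlog = log(100),
                       baseline_mbp_sdlog = 0.15,
                       pulse_pressure_mean = 45,
                       pulse_pressure_sdlog = 0.15,
                       pp_noise_sd = 2,
                       drift_amplitude = 10,
                       band_amplitude_mean = c(1.2, 1.5, 1.8, 2.2, 2.5),
                       band_amplitude_sdlog = 0.4,
                       n_sin_per_band = 3L,
                       white_noise_sd = 1.5,
                       spike_rate_per_h = 1,
                       spike_magnitude = 60,
                       gap_rate_per_h_start = 0.5,
                       gap_rate_per_h_end = 2,
                       gap_duration_meanlog = log(4),
                       gap_duration_sdlog = 0.8,
                       dropout_shape = 1.3,
                       dropout_scale = 1100,
                       cuff_noise_sd = 7,
                       cuff_missing_prob = 0.05,
                       nihss_probs = c(17, 91, 55, 36) / 199,
                       ivt_prob = 0.55,
                       antithrombotic_prob = 0.42,
                       ttr_shape = 1.28,
                       ttr_rate = 0.214,
                       effect_log_or_per_sd = 0.8,
                       effect_bands = 1:4,
                       prob_missing_outcome = 0,
                       prob_missing_covariate = 0,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$ht_prevalence > 0, p$ht_prevalence < 1,
            all(p$band_amplitude_mean >= 0), p$white_noise_sd >= 0,
            p$spike_rate_per_h >= 0, p$cuff_noise_sd >= 0,
            length(p$band_amplitude_mean) == 5L,
            abs(sum(p$nihss_probs) - 1) < 1e-8)
  structure(p, class = "sim_params")
}

# physical period range (minutes) of band b at 1-min sampling
band_period_range <- function(b) c(2^b, 2^(b + 1))

patient_seed <- function(seed, i) {
  (as.numeric(seed) * 1009 + i * 7919) %% 2147483629
}

#' Simulate the continuous recording of one patient
#'
#' The noise-free truth is baseline + slow drift + the five band-limited
#' sinusoid mixtures; the observed finger-cuff series adds white device
#' noise, artefact spikes (shared across channels) and the wear-off
#' missingness/dropout process. SBP and DBP are built from MBP with the
#' pulse-pressure offset so `derive_mbp(SBP, DBP)` reproduces MBP exactly.
#'
#' @param params A [sim_params()].
#' @param latent Per-patient latent state: list with `baseline_mbp`, `pp`
#'   (pulse pressure, mmHg) and `band_amp` (5 amplitudes, mmHg).
#' @param seed Substream seed for this patient's series.
#' @return List with `series` (named list of three continuous `bp_series`),
#'   `truth` (data frame `time`, `SBP`, `DBP`, `MBP` of the noise-free
#'   signal on the 1-min grid) and `spike_minutes` (where artefact spikes
#'   were injected, for QC calibration tests).
#' @export
simulate_continuous <- function(params, latent, seed) {
  set.seed(seed)
  t <- 0:1439
  n <- length(t)

  drift <- (params$drift_amplitude / 2) *
    sin(2 * pi * t / 2880 + stats::runif(1, 0, 2 * pi))
  osc <- numeric(n)
  m <- params$n_sin_per_band
  for (b in 1:5) {
    pr <- band_period_range(b)
    a <- latent$band_amp[b] / sqrt(m)
    # log-uniform frequencies within the central half-octave: a tone at a
    # dyadic band edge belongs half to each neighbouring band under any
    # compact orthogonal filter, so band membership is kept unambiguous by a
    # quarter-octave guard on each side
    guard <- 0.25 * log(2)
    lf <- stats::runif(m, log(1 / pr[2]) + guard, log(1 / pr[1]) - guard)
    freqs <- exp(lf)
    phases <- stats::runif(m, 0, 2 * pi)
    for (k in seq_len(m)) {
      osc <- osc + a * sin(2 * pi * freqs[k] * t + phases[k])
    }
  }
  mbp_truth <- latent$baseline_mbp + drift + osc
  pp <- pmax(latent$pp + stats::rnorm(n, 0, params$pp_noise_sd), 5)
  sbp_truth <- mbp_truth + 2 * pp / 3
  dbp_truth <- mbp_truth - pp / 3

  noise <- function() stats::rnorm(n, 0, params$white_noise_sd)
  obs <- list(SBP = sbp_truth + noise(), DBP = dbp_truth + noise(),
              MBP = mbp_truth + noise())

  n_spk <- stats::rpois(1, params$spike_rate_per_h * 24)
  at <- integer()
  if (n_spk > 0) {
    at <- sample.int(n, min(n_spk, n))
    mag <- sample(c(-1, 1), length(at), replace = TRUE) *
      stats::runif(length(at), 0.8, 1.2) * params$spike_magnitude
    for (ch in names(obs)) obs[[ch]][at] <- obs[[ch]][at] + mag
  }

  valid <- rep(TRUE, n)
  r0 <- params$gap_rate_per_h_start
  r1 <- params$gap_rate_per_h_end
  n_gap <- stats::rpois(1, (r0 + r1) / 2 * 24)
  if (n_gap > 0) {
    # inverse-cdf sampling of onset times under the linear hazard
    u <- stats::runif(n_gap)
    total <- (r0 + r1) / 2 * 24
    if (abs(r1 - r0) < 1e-12) {
      starts <- u * 1440
    } else {
      a_q <- (r1 - r0) / (2 * 1440) / 60
      b_q <- r0 / 60
      starts <- (-b_q + sqrt(b_q^2 + 4 * a_q * u * total)) / (2 * a_q)
    }
    dur <- stats::rlnorm(n_gap, params$gap_duration_meanlog,
                         params$gap_duration_sdlog)
    for (g in seq_len(n_gap)) {
      lo <- max(1L, floor(starts[g]) + 1L)
      hi <- min(n, lo + max(0L, round(dur[g]) - 1L))
      valid[lo:hi] <- FALSE
    }
  }
  dropout <- stats::rweibull(1, params$dropout_shape, params$dropout_scale)
  if (dropout < n) valid[(floor(dropout) + 1L):n] <- FALSE

  series <- lapply(names(obs), function(ch) {
    v <- obs[[ch]]
    v[!valid] <- NA_real_
    bp_series("continuous", ch, t, v)
  })
  names(series) <- names(obs)
  list(series = series,
       truth = data.frame(time = t, SBP = sbp_truth, DBP = dbp_truth,
                          MBP = mbp_truth),
       spike_minutes = sort(t[at]))
}

#' Simulate the intermittent arm-cuff readings of one patient
#'
#' Readings are the noise-free truth at the scheduled minutes plus
#' independent cuff noise; each slot is missing with probability
#' `miss_prob`. Only SBP and DBP are emitted (MBP is derived downstream via
#' the SBP/3 + 2 DBP/3 formula, as for a real cuff).
#'
#' @param truth The `truth` data frame from [simulate_continuous()].
#' @param schedule Scheduled minutes, default [intermittent_schedule()].
#' @param noise_sd Cuff reading noise, mmHg.
#' @param seed Substream seed.
#' @param miss_prob Per-slot missingness probability.
#' @return Named list of two intermittent `bp_series` (SBP, DBP).
#' @export
simulate_intermittent <- function(truth, schedule = intermittent_schedule(),
                                  noise_sd = 7, seed = 1L, miss_prob = 0.05) {
  set.seed(seed)
  idx <- match(schedule, truth$time)
  miss <- stats::runif(length(schedule)) < miss_prob
  mk <- function(ch) {
    v <- truth[[ch]][idx] + stats::rnorm(length(idx), 0, noise_sd)
    v[miss] <- NA_real_
    bp_series("intermittent", ch, schedule, v)
  }
  list(SBP = mk("SBP"), DBP = mk("DBP"))
}

#' Simulate a full cohort with ground truth
#'
#' Cohort-level draws (latent band amplitudes, covariates, outcome) use the
#' global seed; each patient's series uses a derived substream, so the truth
#' table is identical whether or not series are generated and any patient's
#' recording is reproducible independently of cohort size. The outcome is
#' Bernoulli with logit = alpha + beta * z, where z is the cohort-standardised
#' latent sub-32-min band energy, beta = `effect_log_or_per_sd`, and alpha is
#' solved so the mean event probability equals `ht_prevalence`.
#'
#' @param params A [sim_params()].
#' @param include_series Generate the BP series (default) or only latents,
#'   covariates and outcome (fast mode for large Monte-Carlo runs).
#' @return List with `records` (named list of `patient_record`; series empty
#'   in fast mode), `truth` (per-patient latent amplitudes, band energies,
#'   linear predictor, event probability) and `params`.
#' @export
simulate_cohort <- function(params = sim_params(), include_series = TRUE) {
  n <- params$n_patients
  if (n < 1) {
    return(list(records = list(), truth = data.frame(), params = params))
  }
  set.seed(params$seed %% 2147483647)

  amp <- matrix(0, n, 5)
  for (b in 1:5) {
    amp[, b] <- params$band_amplitude_mean[b] *
      exp(stats::rnorm(n, 0, params$band_amplitude_sdlog))
  }
  band_energy <- amp^2 / 2                       # mmHg^2/min, closed form
  e_short <- rowSums(band_energy[, params$effect_bands, drop = FALSE])
  z <- if (n < 2 || stats::sd(e_short) == 0) {
    rep(0, n)            # degenerate latent: outcome reduces to the prevalence
  } else {
    as.numeric(scale(e_short))
  }
  beta <- params$effect_log_or_per_sd
  alpha <- stats::uniroot(function(a) {
    mean(stats::plogis(a + beta * z)) - params$ht_prevalence
  }, c(-30, 30), tol = 1e-12)$root
  p_ht <- stats::plogis(alpha + beta * z)
  ht <- stats::rbinom(n, 1, p_ht) == 1

  baseline <- stats::rlnorm(n, params$baseline_mbp_meanlog,
                            params$baseline_mbp_sdlog)
  pp <- stats::rlnorm(n, log(params$pulse_pressure_mean),
                      params$pulse_pressure_sdlog)
  nihss <- sample.int(4L, n, replace = TRUE, prob = params$nihss_probs)
  adm_mbp <- stats::rlnorm(n, params$baseline_mbp_meanlog,
                           params$baseline_mbp_sdlog)
  ttr <- stats::rgamma(n, params$ttr_shape, params$ttr_rate)
  ivt <- stats::runif(n) < params$ivt_prob
  antit <- stats::runif(n) < params$antithrombotic_prob
  miss_out <- stats::runif(n) < params$prob_missing_outcome
  miss_cov <- stats::runif(n) < params$prob_missing_covariate

  ids <- sprintf("P%04d", seq_len(n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    latent <- list(baseline_mbp = baseline[i], pp = pp[i],
                   band_amp = amp[i, ])
    series <- list()
    if (include_series) {
      cont <- simulate_continuous(params, latent, patient_seed(params$seed, i))
      int <- simulate_intermittent(cont$truth,
                                   noise_sd = params$cuff_noise_sd,
                                   seed = patient_seed(params$seed, i) + 1,
                                   miss_prob = params$cuff_missing_prob)
      series <- c(cont$series, int)
      series <- c(series,
                  list(derive_intermittent_mbp(int$SBP, int$DBP)))
    }
    records[[i]] <- patient_record(
      patient_id = ids[i],
      covariates = list(
        nihss_category = if (miss_cov[i]) NA_integer_ else nihss[i],
        admission_mbp = adm_mbp[i],
        time_to_reperfusion = ttr[i],
        iv_thrombolysis = ivt[i],
        periprocedural_antithrombotic = antit[i]),
      ht_outcome = if (miss_out[i]) NA else ht[i],
      series = series)
  }
  names(records) <- ids

  truth <- data.frame(patient_id = ids, baseline_mbp = baseline,
                      pulse_pressure = pp)
  for (b in 1:5) truth[[sprintf("amp_band%d", b)]] <- amp[, b]
  for (b in 1:5) truth[[sprintf("energy_band%d", b)]] <- band_energy[, b]
  truth$short_band_energy <- e_short
  truth$z_short <- z
  truth$lin_pred <- alpha + beta * z
  truth$p_ht <- p_ht
  truth$ht <- ht

  list(records = records, truth = truth, params = params)
}
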