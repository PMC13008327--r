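test_that("average_to_minute bins sub-minute samples and flags empty minutes", {
  raw <- bp_series("continuous", "SBP",
                   times = c(0.2, 0.7, 7.25, 7.75, 9.5),
                   values = c(110, 112, 118, 122, 130))
  s <- average_to_minute(raw, n_min = 12L)
  expect_equal(s$values[1], 111)
  expect_equal(s$values[8], 120)   # minute 7
  expect_equal(s$values[10], 130)
  expect_false(s$valid[2])         # minute 1: no samples
  expect_equal(sum(s$valid), 3)

  # already-1-min input passes through unchanged
  grid <- bp_series("continuous", "SBP", 0:11, c(100 + 0:10, NA))
  s2 <- average_to_minute(grid, n_min = 12L)
  expect_identical(s2$values[1:11], grid$values[1:11])
  expect_identical(s2$valid, grid$valid)

  empty <- bp_series("continuous", "SBP", numeric(), numeric())
  s3 <- average_to_minute(empty, n_min = 10L)
  expect_equal(sum(s3$valid), 0)
})

test_that("artefact masking flags bounds, steps and spikes without altering values", {
  cfg <- qc_config()
  t <- 0:59
  x <- rep(100, 60)
  x[31] <- 350                       # impossible SBP
  s <- remove_artifacts(bp_series("continuous", "SBP", t, x), cfg)
  expect_false(s$valid[31])
  expect_identical(s$values, x)      # masked, never modified
  expect_equal(unname(attr(s, "qc_flags")["bounds"]), 1)

  # clean in-bounds sinusoid: negative control, nothing masked
  xs <- 100 + 15 * sin(2 * pi * t / 20)
  s2 <- remove_artifacts(bp_series("continuous", "SBP", t, xs), cfg)
  expect_equal(sum(!s2$valid), 0)

  # +60 mmHg single-sample spike in a flat series
  x3 <- rep(100, 60)
  x3[31] <- 160
  s3 <- remove_artifacts(bp_series("continuous", "SBP", t, x3), cfg)
  expect_false(s3$valid[31])
  expect_equal(sum(!s3$valid), 1)    # the return step is not flagged
})

test_that("the rolling rule agrees with a scripted median/MAD oracle", {
  cfg <- qc_config(max_step_mmHg = 1e6)  # isolate the rolling stage
  set.seed(7)
  t <- 0:119
  x <- 100 + 5 * sin(2 * pi * t / 30) + rnorm(120, 0, 1)
  x[c(40, 80)] <- x[c(40, 80)] + 60      # spikes (1-based positions)
  s <- remove_artifacts(bp_series("continuous", "SBP", t, x), cfg)

  # independent loop implementation of the Hampel rule, edge shrinkage and all
  half <- (cfg$rolling_window_min - 1) / 2
  flag_oracle <- vapply(seq_along(x), function(i) {
    w <- x[max(1, i - half):min(length(x), i + half)]
    med <- median(w)
    madv <- median(abs(w - med))
    abs(x[i] - med) > cfg$rolling_mad_mult * max(madv, cfg$mad_floor_mmHg)
  }, TRUE)
  expect_identical(!s$valid, flag_oracle)
  expect_false(s$valid[40])
  expect_false(s$valid[80])
  expect_lte(sum(!s$valid), 4)           # spikes plus at most stray noise
})

test_that("Gaussian gap imputation matches an independent convolution oracle", {
  cfg <- qc_config()
  t <- 0:59
  x <- 100 + 0.5 * t                 # linear ramp
  x[21:23] <- NA                     # 3-min gap (minutes 20-22)
  s <- impute_short_gaps(bp_series("continuous", "SBP", t, x), cfg)
  expect_true(all(s$valid[21:23]))
  expect_true(all(s$imputed[21:23]))
  expect_equal(sum(s$imputed), 3)

  # independent oracle: mask-normalised discrete Gaussian convolution
  valid0 <- !is.na(x)
  radius <- ceiling(4 * cfg$impute_sigma_min)
  oracle <- function(i) {
    k <- (i - radius):(i + radius)
    k <- k[k >= 1 & k <= 60 & valid0[pmax(pmin(k, 60), 1)]]
    w <- dnorm(k - i, sd = cfg$impute_sigma_min)
    sum(w * x[k]) / sum(w)
  }
  for (i in 21:23) expect_equal(s$values[i], oracle(i), tolerance = 1e-12)
  # filled values lie between the neighbouring observed values
  expect_true(all(s$values[21:23] > x[20] & s$values[21:23] < x[24]))

  # a 10-min gap stays missing; a 5-min gap is NOT imputed (strict < 5)
  x2 <- 100 + 0.5 * t
  x2[31:40] <- NA
  x2[11:15] <- NA
  s2 <- impute_short_gaps(bp_series("continuous", "SBP", t, x2), cfg)
  expect_false(any(s2$valid[31:40]))
  expect_false(any(s2$valid[11:15]))

  # gapless series is untouched
  s3 <- impute_short_gaps(bp_series("continuous", "SBP", t, 100 + 0.5 * t), cfg)
  expect_equal(sum(s3$imputed), 0)

  expect_warning(
    impute_short_gaps(bp_series("continuous", "SBP", 0:5, rep(NA_real_, 6)), cfg),
    "no valid")
})

test_that("longest_contiguous_window applies the 128-min rule with earliest ties", {
  cfg <- qc_config()
  w <- analysis_window("P1")
  mk <- function(mask) {
    v <- rep(NA_real_, 480)
    v[mask] <- 100
    bp_series("continuous", "MBP", 0:479, v)
  }
  # runs of 100 and 140 valid minutes: the 140-min run wins
  s <- mk(c(1:100, 151:290))
  expect_equal(longest_contiguous_window(s, w, cfg), c(150, 290))
  # 127-min longest run: below threshold
  expect_null(longest_contiguous_window(mk(1:127), w, cfg))
  # fully valid period
  expect_equal(longest_contiguous_window(mk(1:480), w, cfg), c(0, 480))
  # equal 150-min runs: earliest start wins
  s2 <- mk(c(1:150, 161:310))
  expect_equal(longest_contiguous_window(s2, w, cfg), c(0, 150))
})

test_that("QC masking conserves samples and imputation only fills short gaps", {
  set.seed(31)
  for (rep in 1:10) {
    sim <- simulate_cohort(sim_params(n_patients = 1, seed = 300 + rep))
    raw <- sim$records[[1]]$series[["continuous.SBP"]]
    cfg <- qc_config()
    a <- remove_artifacts(average_to_minute(raw), cfg)
    b <- impute_short_gaps(a, cfg)
    # sample count conserved; masking is one-directional
    expect_length(b$values, 1440)
    expect_true(all(a$valid <= average_to_minute(raw)$valid))
    # imputation never removes an observed valid sample
    expect_true(all(b$valid >= a$valid))
    expect_equal(sum(b$valid & !b$imputed), sum(a$valid))
    # imputed runs are all strictly shorter than the gap limit
    if (any(b$imputed)) {
      r <- rle(b$imputed)
      expect_true(all(r$lengths[r$values] < cfg$max_impute_gap_min))
    }
  }
})

test_that("eligibility reasons match the documented six-patient fixture", {
  cohort <- lapply(qc_fixture_cohort(), preprocess_record)
  w <- analysis_window("P1")
  for (id in names(cohort)) {
    e <- assess_eligibility(cohort[[id]], w)
    expect_identical(sort(e$reasons), sort(qc_fixture_expected[[id]]),
                     label = paste("reasons for", id))
    expect_identical(e$eligible, length(qc_fixture_expected[[id]]) == 0L,
                     label = paste("eligibility of", id))
  }
})

test_that("eligibility is monotone in added valid data", {
  w <- analysis_window("P1")
  base_mask <- rep(FALSE, 480)
  base_mask[1:150] <- TRUE
  set.seed(5)
  for (i in 1:20) {
    extra <- base_mask
    extra[sample(which(!base_mask), 40)] <- TRUE
    r1 <- preprocess_record(toy_record("X", base_mask, n_int_valid = 8L))
    r2 <- preprocess_record(toy_record("X", extra, n_int_valid = 12L))
    e1 <- assess_eligibility(r1, w)
    e2 <- assess_eligibility(r2, w)
    if (e1$eligible) expect_true(e2$eligible)
  }
})

test_that("missing outcome and covariates are detected independently of BP data", {
  mask <- rep(TRUE, 480)
  r <- toy_record("Y", mask)
  r$covariates$admission_mbp <- NA_real_
  e <- assess_eligibility(preprocess_record(r), analysis_window("P1"))
  expect_false(e$eligible)
  expect_identical(e$reasons, "missing_covariates")
})
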