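test_that("derive_mbp matches the one-third/two-thirds weighting", {
  expect_equal(derive_mbp(120, 60), 80)
  expect_equal(derive_mbp(185, 110), 135)
  expect_equal(derive_mbp(100, 100), 100)
  expect_error(derive_mbp(90, 100), "sbp")
  expect_error(derive_mbp(50, -10), "dbp")
})

test_that("derive_mbp is monotone in both arguments and bracketed by inputs", {
  set.seed(42)
  for (i in 1:200) {
    dbp <- runif(1, 40, 120)
    sbp <- dbp + runif(1, 0, 120)
    m <- derive_mbp(sbp, dbp)
    expect_gte(m, dbp)
    expect_lte(m, sbp)
    expect_gt(derive_mbp(sbp + 1, dbp), m)
    expect_gt(derive_mbp(sbp, min(dbp + 1, sbp)), m - 1e-12)
  }
})

test_that("bp_series validates its invariants", {
  s <- bp_series("continuous", "SBP", 0:4, c(120, 121, NA, 119, 118))
  expect_s3_class(s, "bp_series")
  expect_equal(s$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(bp_series("continuous", "SBP", c(0, 2, 1), 1:3), "increasing")
  expect_error(bp_series("continuous", "SBP", 0:2, 1:2), "length")
  expect_error(bp_series("continuous", "XBP", 0:2, 1:3))
})

test_that("the cuff schedule enumerates 20/8/8 slots across the periods", {
  expect_length(intermittent_schedule(), 36)
  expect_length(intermittent_schedule(analysis_window("P1")), 20)
  expect_length(intermittent_schedule(analysis_window("P2")), 8)
  expect_length(intermittent_schedule(analysis_window("P3")), 8)
  expect_equal(intermittent_schedule(analysis_window("P1"))[1:10],
               c(0, 15, 30, 45, 60, 75, 90, 105, 120, 150))
})

test_that("analysis windows are half-open 8-h periods plus the full day", {
  for (lab in c("P1", "P2", "P3")) {
    w <- analysis_window(lab)
    expect_equal(w$end_min - w$start_min, 480)
  }
  expect_equal(analysis_window("FULL24")$end_min, 1440)
})

test_that("nihss_category supports both published bin conventions", {
  expect_equal(nihss_category(c(0, 3, 4, 14, 15, 20, 21, 42)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(nihss_category(c(4, 5, 15, 16, 21), edges = c(4, 15, 20)),
               c(1L, 2L, 2L, 3L, 4L))
})

test_that("load_cohort round-trips a complete two-patient fixture", {
  d <- withr::local_tempdir()
  paths <- write_toy_cohort_csvs(d)
  lc <- load_cohort(paths$recordings, paths$clinical)
  expect_length(lc$records, 2)
  expect_equal(lc$report$n_coerced_cells, 0)
  # 5 stored series + derived intermittent MBP
  expect_length(lc$records[["A"]]$series, 6)
  smbp <- lc$records[["A"]]$series[["intermittent.MBP"]]
  ssbp <- lc$records[["A"]]$series[["intermittent.SBP"]]
  sdbp <- lc$records[["A"]]$series[["intermittent.DBP"]]
  expect_equal(smbp$values, ssbp$values / 3 + 2 * sdbp$values / 3)

  # write/load round trip is lossless
  write_cohort(lc$records, file.path(d, "r2.csv"), file.path(d, "c2.csv"))
  lc2 <- load_cohort(file.path(d, "r2.csv"), file.path(d, "c2.csv"))
  for (id in names(lc$records)) {
    for (key in names(lc$records[[id]]$series)) {
      expect_identical(lc2$records[[id]]$series[[key]]$values,
                       lc$records[[id]]$series[[key]]$values)
    }
    expect_identical(lc2$records[[id]]$covariates, lc$records[[id]]$covariates)
  }
})

test_that("load_cohort handles bad cells, orphans and schema violations", {
  d <- withr::local_tempdir()
  # a non-numeric pressure cell becomes an invalid sample and is counted
  paths <- write_toy_cohort_csvs(d, tamper = function(rec) {
    rec$value_mmHg[3] <- "garbled"
    rec
  })
  lc <- load_cohort(paths$recordings, paths$clinical)
  expect_equal(lc$report$n_coerced_cells, 1)
  all_valid <- unlist(lapply(lc$records, function(r) {
    lapply(r$series[!grepl("intermittent.MBP", names(r$series))],
           function(s) s$valid)
  }))
  expect_equal(sum(!all_valid), 1)

  # a patient present only in the recordings file is reported, not loaded
  paths <- write_toy_cohort_csvs(d, tamper = function(rec) {
    extra <- rec[rec$patient_id == "A", ][1:3, ]
    extra$patient_id <- "GHOST"
    extra$time_min <- extra$time_min + 100
    rbind(rec, extra)
  })
  lc <- load_cohort(paths$recordings, paths$clinical)
  expect_equal(lc$report$only_in_recordings, "GHOST")
  expect_false("GHOST" %in% names(lc$records))

  # duplicate (patient, source, channel, time) is an integrity error
  paths <- write_toy_cohort_csvs(d, tamper = function(rec) rbind(rec, rec[1, ]))
  expect_error(load_cohort(paths$recordings, paths$clinical), "duplicate")

  # a missing required column is named in the schema error
  paths <- write_toy_cohort_csvs(d, tamper = function(rec) {
    rec$value_mmHg <- NULL
    rec
  })
  expect_error(load_cohort(paths$recordings, paths$clinical), "value_mmHg")
})

test_that("write_table round-trips bit-identically and refuses empty input", {
  d <- withr::local_tempdir()
  ft <- data.frame(patient_id = c("A", "B"),
                   cont_SBP_sd_mmHg = c(pi, exp(1) / 7),
                   cont_MBP_wav_8_16_mmHg2_per_min = c(1 / 3, 2e-17))
  p <- file.path(d, "ft.csv")
  write_table(ft, p)
  back <- read_table(p)
  expect_identical(back$cont_SBP_sd_mmHg, ft$cont_SBP_sd_mmHg)
  expect_identical(back$cont_MBP_wav_8_16_mmHg2_per_min,
                   ft$cont_MBP_wav_8_16_mmHg2_per_min)

  p2 <- file.path(d, "empty.csv")
  expect_error(write_table(ft[0, ], p2), "empty")
  expect_false(file.exists(p2))
})

test_that("OR result tables carry the documented schema", {
  set.seed(9)
  ft <- data.frame(patient_id = sprintf("P%02d", 1:60), f1 = rnorm(60))
  y <- rbinom(60, 1, 0.4)
  res <- or_per_sd(ft, y, feature = "f1")
  expect_true(all(c("or", "ci_low", "ci_high", "p", "model", "n_used")
                  %in% names(res)))
  d <- withr::local_tempdir()
  write_table(res, file.path(d, "or.csv"))
  expect_setequal(names(read_table(file.path(d, "or.csv"))), names(res))
})
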