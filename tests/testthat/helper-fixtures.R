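# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# constant-valued continuous channel on the P1 grid with a crafted validity
# mask (length 480); values outside P1 left missing
const_cont_series <- function(channel, mask480, value = NULL) {
  if (is.null(value)) {
    value <- c(SBP = 120, DBP = 70, MBP = 120 / 3 + 2 * 70 / 3)[[channel]]
  }
  vals <- rep(NA_real_, 480)
  vals[mask480] <- value
  bp_series("continuous", channel, 0:479, vals)
}

# intermittent SBP/DBP readings on the P1 schedule with n_valid of the 20
# slots present
toy_intermittent <- function(n_valid) {
  slots <- intermittent_schedule(analysis_window("P1"))
  mk <- function(ch, value) {
    vals <- rep(NA_real_, length(slots))
    if (n_valid > 0) vals[seq_len(n_valid)] <- value
    bp_series("intermittent", ch, slots, vals)
  }
  list(mk("SBP", 120), mk("DBP", 70))
}

complete_covariates <- function() {
  list(nihss_category = 2L, admission_mbp = 100,
       time_to_reperfusion = 5, iv_thrombolysis = TRUE,
       periprocedural_antithrombotic = FALSE)
}

toy_record <- function(id, mask480, ht = FALSE, n_int_valid = 20L,
                       covariates = complete_covariates()) {
  series <- c(lapply(c("SBP", "DBP", "MBP"),
                     function(ch) const_cont_series(ch, mask480)),
              toy_intermittent(n_int_valid))
  patient_record(id, covariates, ht, series)
}

# The six-patient QC fixture: crafted gaps of 3/5/10 min, longest runs of
# 127 vs 128 valid min, 20%/35% valid fractions, one missing outcome.
# Documented expected labels (window P1):
#   QA fully valid                                -> eligible
#   QB fully valid, outcome NA                    -> missing_outcome
#   QC two 127-min runs (53% valid)               -> no_contiguous_window
#   QD 128-min run + 20 min (30.8% valid),
#      7/20 cuff readings (35%)                   -> eligible
#   QE 96 valid min (20%), 5/20 cuff (25%)        -> insufficient_intermittent,
#                                                    insufficient_continuous,
#                                                    no_contiguous_window
#   QF gaps of 3 (imputed), 5 and 10 min          -> eligible
qc_fixture_cohort <- function() {
  m <- function(...) { v <- rep(FALSE, 480); for (r in list(...)) v[r] <- TRUE; v }
  list(
    QA = toy_record("QA", m(1:480)),
    QB = toy_record("QB", m(1:480), ht = NA),
    QC = toy_record("QC", m(1:127, 138:264)),
    QD = toy_record("QD", m(1:128, 201:220), n_int_valid = 7L),
    QE = toy_record("QE", m(1:96), n_int_valid = 5L),
    QF = toy_record("QF", m(1:100, 104:200, 206:300, 311:480))
  )
}

qc_fixture_expected <- list(
  QA = character(),
  QB = "missing_outcome",
  QC = "no_contiguous_window",
  QD = character(),
  QE = c("insufficient_intermittent", "insufficient_continuous",
         "no_contiguous_window"),
  QF = character()
)

# independent periodogram oracle: dyadic band (level) holding the most
# spectral power of x; level j covers periods [2^j, 2^(j+1)) minutes
periodogram_band_argmax <- function(x, n_levels = 5L) {
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) / n
  keep <- freq > 0 & freq <= 0.5
  lev <- floor(log2(1 / freq[keep]))
  ok <- lev >= 1 & lev <= n_levels
  sums <- tapply(pw[keep][ok], lev[ok], sum)
  as.integer(names(sums)[which.max(sums)])
}

# independent concordant-pair AUC oracle
auc_pair_oracle <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]
  sn <- scores[!y]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# write a small two-patient cohort CSV pair; returns the paths
write_toy_cohort_csvs <- function(dir, tamper = NULL) {
  rec <- expand.grid(patient_id = c("A", "B"),
                     source = c("continuous", "intermittent"),
                     channel = c("SBP", "DBP", "MBP"),
                     time_min = c(0, 1, 2), stringsAsFactors = FALSE)
  rec <- rec[!(rec$source == "intermittent" & rec$channel == "MBP"), ]
  rec$value_mmHg <- ifelse(rec$channel == "SBP", 120,
                           ifelse(rec$channel == "DBP", 70, 86.7)) +
    as.numeric(factor(rec$patient_id)) + rec$time_min / 10
  if (!is.null(tamper)) rec <- tamper(rec)
  clin <- data.frame(patient_id = c("A", "B"), nihss_category = c(2L, 3L),
                     admission_mbp = c(100, 110),
                     time_to_reperfusion_h = c(4.5, 6),
                     iv_thrombolysis = c(1L, 0L),
                     periprocedural_antithrombotic = c(0L, 1L),
                     ht_outcome = c(0L, 1L))
  rp <- file.path(dir, "recordings.csv")
  cp <- file.path(dir, "clinical.csv")
  utils::write.csv(rec, rp, row.names = FALSE)
  utils::write.csv(clin, cp, row.names = FALSE)
  list(recordings = rp, clinical = cp)
}
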