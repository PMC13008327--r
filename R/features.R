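# Statistical variability features and the per-window feature table.

CHANNEL_THRESHOLDS <- c(SBP = 185, DBP = 110, MBP = 130)

#' Statistical variability features of a series within a window
#'
#' Computed on the observed (valid and non-imputed) samples only: mean,
#' maximum, range, sample SD, coefficient of variation (100*sd/mean) and the
#' percentage of samples above the channel's absolute threshold (SBP > 185,
#' DBP > 110, MBP > 130 mmHg).
#'
#' @param series A `bp_series`.
#' @param window An [analysis_window()].
#' @param threshold Absolute threshold in mmHg; defaults to the channel's
#'   standard threshold.
#' @return Named list: `mean`, `maximum`, `range`, `sd` (mmHg), `cv`,
#'   `prop_above_threshold` (%), `n_obs`, `available`. With fewer than two
#'   observed samples the feature values are `NA` and `available` is `FALSE`.
#' @export
stat_features <- function(series, window,
                          threshold = CHANNEL_THRESHOLDS[[series$channel]]) {
  sel <- series$times >= window$start_min & series$times < window$end_min
  obs <- sel & series$valid & !series$imputed
  x <- series$values[obs]
  n <- length(x)
  if (n < 2) {
    return(list(mean = NA_real_, maximum = NA_real_, range = NA_real_,
                sd = NA_real_, cv = NA_real_, prop_above_threshold = NA_real_,
                n_obs = n, available = FALSE))
  }
  m <- mean(x)
  s <- stats::sd(x)
  list(mean = m,
       maximum = max(x),
       range = max(x) - min(x),
       sd = s,
       cv = if (m > 0) 100 * s / m else NA_real_,
       prop_above_threshold = 100 * mean(x > threshold),
       n_obs = n,
       available = TRUE)
}

STAT_NAMES <- c(mean = "mmHg", maximum = "mmHg", range = "mmHg", sd = "mmHg",
                cv = "pct", prop_above_threshold = "pct")

feature_col <- function(source, channel, stat) {
  pre <- if (source == "continuous") "cont" else "int"
  sprintf("%s_%s_%s_%s", pre, channel, stat, STAT_NAMES[[stat]])
}

wavelet_col <- function(channel, label) {
  sprintf("cont_%s_wav_%s_mmHg2_per_min", channel, label)
}

#' Names of the feature columns produced by [build_feature_table()]
#'
#' @param wav_cfg A [wavelet_config()] (determines the band labels).
#' @return Character vector of 51 column names: 2 sources x 3 channels x 6
#'   statistical features, plus 3 channels x 5 band energies for the
#'   continuous source.
#' @export
feature_column_names <- function(wav_cfg = wavelet_config()) {
  cols <- character()
  for (src in c("continuous", "intermittent")) {
    for (ch in c("SBP", "DBP", "MBP")) {
      for (st in names(STAT_NAMES)) cols <- c(cols, feature_col(src, ch, st))
    }
  }
  for (ch in c("SBP", "DBP", "MBP")) {
    for (lab in band_labels(wav_cfg)) cols <- c(cols, wavelet_col(ch, lab))
  }
  cols
}

#' Per-patient variability feature table for one window
#'
#' One row per eligible patient. Statistical features come from observed
#' samples of both sources; wavelet band energies come from each continuous
#' channel's longest contiguous (imputed) span within the window. Cells that
#' cannot be computed (fewer than two observed samples, or no qualifying
#' span) are `NA`; the row is retained.
#'
#' @param records Named list of preprocessed `patient_record`.
#' @param window An [analysis_window()] or window label.
#' @param qc_cfg A [qc_config()].
#' @param wav_cfg A [wavelet_config()].
#' @param eligibility Optional precomputed eligibility data frame from
#'   [eligibility_report()] for this window; computed when `NULL`.
#' @return Data frame of class `feature_table` with `patient_id` plus the
#'   columns of [feature_column_names()]; attributes `window`, `family`,
#'   `band_convention`.
#' @export
build_feature_table <- function(records, window, qc_cfg = qc_config(),
                                wav_cfg = wavelet_config(),
                                eligibility = NULL) {
  if (is.character(window)) window <- analysis_window(window)
  if (is.null(eligibility)) {
    eligibility <- eligibility_report(records, window$label, qc_cfg)
  } else {
    eligibility <- eligibility[eligibility$window == window$label, , drop = FALSE]
  }
  keep <- eligibility$patient_id[eligibility$eligible]
  if (!length(keep)) stop("build_feature_table: no eligible patients")

  cols <- feature_column_names(wav_cfg)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    r <- records[[keep[i]]]
    vals <- stats::setNames(rep(NA_real_, length(cols)), cols)
    for (src in c("continuous", "intermittent")) {
      for (ch in c("SBP", "DBP", "MBP")) {
        s <- r$series[[series_key(src, ch)]]
        if (is.null(s)) next
        sf <- stat_features(s, window)
        if (sf$available) {
          for (st in names(STAT_NAMES)) {
            vals[feature_col(src, ch, st)] <- sf[[st]]
          }
        }
        if (src == "continuous") {
          span <- longest_contiguous_window(s, window, qc_cfg)
          if (!is.null(span)) {
            we <- wavelet_band_energies(s, span, wav_cfg,
                                        min_span = qc_cfg$min_contig_min)
            labs <- band_labels(wav_cfg)
            for (k in seq_along(labs)) {
              vals[wavelet_col(ch, labs[k])] <- we$band_energy[[k]]
            }
          }
        }
      }
    }
    rows[[i]] <- c(list(patient_id = r$patient_id), as.list(vals))
  }
  out <- do.call(rbind, lapply(rows, function(z) {
    as.data.frame(z, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  attr(out, "window") <- window$label
  attr(out, "family") <- wav_cfg$family
  attr(out, "band_convention") <- wav_cfg$band_convention
  class(out) <- c("feature_table", class(out))
  out
}

#' Outcome and covariates for the patients of a feature table
#'
#' @param records Named list of `patient_record`.
#' @param feature_table A `feature_table` (or any data frame with
#'   `patient_id`).
#' @return List with `outcome` (0/1 integer) and `covariates` (data frame
#'   with the five adjustment covariates), row order matching the table.
#' @export
outcome_covariates <- function(records, feature_table) {
  ids <- feature_table$patient_id
  outcome <- vapply(ids, function(id) as.integer(records[[id]]$ht_outcome), 0L)
  cov <- do.call(rbind, lapply(ids, function(id) {
    cv <- records[[id]]$covariates
    data.frame(nihss_category = cv$nihss_category,
               admission_mbp = cv$admission_mbp,
               time_to_reperfusion = cv$time_to_reperfusion,
               iv_thrombolysis = as.integer(cv$iv_thrombolysis),
               periprocedural_antithrombotic = as.integer(cv$periprocedural_antithrombotic))
  }))
  list(outcome = unname(outcome), covariates = cov)
}
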