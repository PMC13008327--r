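#' Quality-control configuration
#'
#' Defaults implement a three-stage deterministic artefact mask on the 1-min
#' continuous signal (physiological plausibility bounds, absolute step-change
#' limit between adjacent minutes, Hampel-style rolling-median deviation rule),
#' Gaussian-filter imputation of gaps strictly shorter than 5 min, a 128-min
#' minimum contiguous window for wavelet decomposition, and the 30% minimum
#' valid-data fraction of the per-period eligibility ladder.
#'
#' @param bounds Named list of `c(lo, hi)` plausibility bounds per channel, mmHg.
#' @param max_step_mmHg Maximum absolute change between adjacent valid minutes;
#'   the later sample of a larger jump is flagged.
#' @param rolling_window_min Centred window (odd, minutes) of the rolling
#'   median/MAD outlier rule.
#' @param rolling_mad_mult Flag a sample when
#'   `|x - rolling median| > mult * rolling MAD`.
#' @param mad_floor_mmHg Lower floor on the rolling MAD so locally flat
#'   signals do not flag measurement-resolution jitter.
#' @param max_impute_gap_min Gaps of invalid minutes strictly shorter than
#'   this are imputed; gaps of exactly this length or longer are left missing.
#' @param min_contig_min Minimum contiguous run of valid minutes required for
#'   wavelet decomposition.
#' @param min_valid_fraction Minimum fraction of valid data per window, for
#'   both the continuous and the intermittent source.
#' @param impute_sigma_min Standard deviation (minutes) of the Gaussian
#'   smoothing kernel used for gap imputation.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(bounds = list(SBP = c(40, 300), DBP = c(20, 200),
                                    MBP = c(30, 250)),
                      max_step_mmHg = 40,
                      rolling_window_min = 15,
                      rolling_mad_mult = 5,
                      mad_floor_mmHg = 0.1,
                      max_impute_gap_min = 5,
                      min_contig_min = 128,
                      min_valid_fraction = 0.30,
                      impute_sigma_min = 2.5) {
  stopifnot(max_impute_gap_min < min_contig_min,
            min_valid_fraction > 0, min_valid_fraction < 1,
            rolling_window_min %% 2 == 1, impute_sigma_min > 0)
  structure(list(bounds = bounds, max_step_mmHg = max_step_mmHg,
                 rolling_window_min = rolling_window_min,
                 rolling_mad_mult = rolling_mad_mult,
                 mad_floor_mmHg = mad_floor_mmHg,
                 max_impute_gap_min = max_impute_gap_min,
                 min_contig_min = min_contig_min,
                 min_valid_fraction = min_valid_fraction,
                 impute_sigma_min = impute_sigma_min),
            class = "qc_config")
}

#' Average a sub-minute series onto the regular 1-min grid
#'
#' Each output minute t holds the mean of the valid raw samples with
#' timestamps in \[t, t+1); minutes with no valid sample are invalid. Input
#' already on the integer-minute grid passes through unchanged.
#'
#' @param raw A continuous `bp_series` with times in \[0, 1440).
#' @param n_min Grid length in minutes (default the full 24-h day).
#' @return A `bp_series` with `times = 0:(n_min-1)`.
#' @export
average_to_minute <- function(raw, n_min = 1440L) {
  grid <- seq.int(0L, n_min - 1L)
  # fast path: input already on the full integer-minute grid
  if (length(raw$times) == n_min && identical(as.numeric(raw$times),
                                              as.numeric(grid))) {
    vals <- raw$values
    vals[!raw$valid] <- NA_real_
    return(bp_series(raw$source, raw$channel, grid, vals))
  }
  vals <- rep(NA_real_, n_min)
  ok <- raw$valid & raw$times >= 0 & raw$times < n_min
  if (any(ok)) {
    bin <- floor(raw$times[ok])
    sums <- rowsum(raw$values[ok], bin)
    cnts <- rowsum(rep(1, sum(ok)), bin)
    vals[as.integer(rownames(sums)) + 1L] <- sums / cnts
  }
  bp_series(raw$source, raw$channel, grid, vals)
}

#' Mask artefacts and outliers in a 1-min continuous series
#'
#' Three deterministic stages, applied in order and logged individually:
#' (1) plausibility bounds per channel; (2) absolute first-difference limit —
#' a jump larger than `max_step_mmHg` between adjacent valid minutes flags
#' the later sample; (3) rolling Hampel rule: a valid sample is flagged when
#' it deviates from its centred window's median (window of
#' `rolling_window_min` valid samples, shrunk at the edges) by more than
#' `rolling_mad_mult` times that window's median absolute deviation.
#' Values are never altered, only the validity mask.
#'
#' @param series A `bp_series` on the 1-min grid.
#' @param cfg A [qc_config()].
#' @return The series with updated `valid`; attribute `qc_flags` holds the
#'   per-rule flag counts.
#' @export
remove_artifacts <- function(series, cfg = qc_config()) {
  x <- series$values
  v <- series$valid
  b <- cfg$bounds[[series$channel]]

  f_bounds <- v & (x < b[1] | x > b[2])
  v <- v & !f_bounds

  f_step <- rep(FALSE, length(x))
  idx <- which(v)
  if (length(idx) > 1) {
    adj <- idx[-1][diff(idx) == 1L]  # later sample of adjacent valid pairs
    jump <- rep(FALSE, length(x))
    jump[adj] <- abs(x[adj] - x[adj - 1L]) > cfg$max_step_mmHg
    # flag the later sample of a jump unless its predecessor was itself a
    # jump (the return step after an isolated spike is a good sample)
    f_step <- jump & !c(FALSE, jump[-length(jump)])
    v <- v & !f_step
  }

  # Hampel statistics run over the compressed sequence of valid samples so
  # every window holds real measurements; the MAD is taken against the
  # window's own median (a double running median collapses to zero on
  # monotone stretches and flags ordinary noise)
  f_roll <- rep(FALSE, length(x))
  if (sum(v) >= cfg$rolling_window_min) {
    iv <- which(v)
    xv <- x[iv]
    rs <- rolling_med_mad(xv, cfg$rolling_window_min)
    thr <- cfg$rolling_mad_mult * pmax(rs$mad, cfg$mad_floor_mmHg)
    f_roll[iv[abs(xv - rs$med) > thr]] <- TRUE
    v <- v & !f_roll
  }

  out <- series
  out$valid <- v
  out$imputed <- out$imputed & v
  attr(out, "qc_flags") <- c(bounds = sum(f_bounds), step = sum(f_step),
                             rolling = sum(f_roll))
  out
}

# run-length encoding of the validity mask -> data frame of runs
validity_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends,
             len = r$lengths, valid = r$values)
}

gaussian_kernel <- function(sigma) {
  radius <- ceiling(4 * sigma)
  w <- stats::dnorm(seq(-radius, radius), sd = sigma)
  w / sum(w)
}

# mask-normalised Gaussian smoothing of the valid samples, evaluated on the
# whole grid; positions with zero kernel mass over valid samples return NA
gaussian_smooth_masked <- function(x, v, sigma) {
  w <- gaussian_kernel(sigma)
  xz <- ifelse(v, x, 0)
  # zero padding so positions near the ends keep a defined (renormalised) value
  pad <- (length(w) - 1L) / 2L
  xp <- c(rep(0, pad), xz, rep(0, pad))
  vp <- c(rep(0, pad), as.numeric(v), rep(0, pad))
  num <- stats::filter(xp, w, sides = 2)[(pad + 1L):(pad + length(x))]
  den <- stats::filter(vp, w, sides = 2)[(pad + 1L):(pad + length(x))]
  out <- as.numeric(num) / as.numeric(den)
  out[as.numeric(den) <= 0] <- NA_real_
  out
}

#' Impute short gaps with a Gaussian-filtered version of the signal
#'
#' Runs of invalid minutes strictly shorter than `cfg$max_impute_gap_min`
#' are filled with the value of a Gaussian-smoothed (mask-normalised) version
#' of the valid signal at those minutes, and marked `valid = TRUE`,
#' `imputed = TRUE`. Longer gaps are untouched, so statistical features can
#' keep using observed samples only while wavelet decomposition receives a
#' gap-free contiguous span.
#'
#' @param series A `bp_series` on the 1-min grid with artefacts already masked.
#' @param cfg A [qc_config()].
#' @return The series with short gaps filled.
#' @export
impute_short_gaps <- function(series, cfg = qc_config()) {
  v <- series$valid
  if (!any(v)) {
    warning("impute_short_gaps: series has no valid samples; returned unchanged")
    return(series)
  }
  runs <- validity_runs(v)
  gaps <- runs[!runs$valid & runs$len < cfg$max_impute_gap_min, , drop = FALSE]
  if (!nrow(gaps)) return(series)
  sm <- gaussian_smooth_masked(series$values, v, cfg$impute_sigma_min)
  out <- series
  for (i in seq_len(nrow(gaps))) {
    pos <- gaps$start[i]:gaps$end[i]
    fill <- sm[pos]
    ok <- !is.na(fill)
    pos <- pos[ok]
    out$values[pos] <- fill[ok]
    out$valid[pos] <- TRUE
    out$imputed[pos] <- TRUE
  }
  out
}

#' Longest contiguous run of valid minutes within a window
#'
#' @param series A `bp_series` on the 1-min grid, imputation applied.
#' @param window An [analysis_window()].
#' @param cfg A [qc_config()]; runs shorter than `min_contig_min` yield `NULL`.
#' @return `c(start_min, end_min)` (half-open, minutes) of the longest run,
#'   earliest on ties, or `NULL` if no run reaches the minimum length.
#' @export
longest_contiguous_window <- function(series, window, cfg = qc_config()) {
  sel <- series$times >= window$start_min & series$times < window$end_min
  if (!any(sel)) return(NULL)
  t_sub <- series$times[sel]
  runs <- validity_runs(series$valid[sel])
  runs <- runs[runs$valid, , drop = FALSE]
  if (!nrow(runs) || max(runs$len) < cfg$min_contig_min) return(NULL)
  best <- runs[which.max(runs$len), ]  # which.max takes the earliest tie
  c(t_sub[best$start], t_sub[best$end] + 1)
}

#' Per-window eligibility assessment
#'
#' A patient enters the analysis of a window only with (i) outcome and all
#' five adjustment covariates available, (ii) at least `min_valid_fraction`
#' valid data in both sources — continuous: observed (non-imputed) valid
#' minutes over the window length; intermittent: valid readings over the
#' scheduled slots in the window — and (iii) a contiguous run of
#' `min_contig_min` valid minutes (imputed minutes count) in every continuous
#' channel. An intermittent reading is valid when both SBP and DBP are valid
#' at the slot.
#'
#' @param record A preprocessed `patient_record`.
#' @param window An [analysis_window()].
#' @param cfg A [qc_config()].
#' @return A list (class `eligibility_report`) with `patient_id`, `window`,
#'   `eligible`, `reasons` (character vector, empty when eligible).
#' @export
assess_eligibility <- function(record, window, cfg = qc_config()) {
  reasons <- character()
  if (is.na(record$ht_outcome)) reasons <- c(reasons, "missing_outcome")
  cv <- record$covariates[covariate_names()]
  if (any(vapply(cv, function(z) is.null(z) || is.na(z), TRUE))) {
    reasons <- c(reasons, "missing_covariates")
  }

  slots <- intermittent_schedule(window)
  n_valid_int <- Inf
  for (ch in c("SBP", "DBP")) {
    s <- record$series[[series_key("intermittent", ch)]]
    nv <- if (is.null(s)) 0L else {
      sum(s$valid[s$times %in% slots])
    }
    n_valid_int <- min(n_valid_int, nv)
  }
  if (length(slots) && n_valid_int / length(slots) < cfg$min_valid_fraction) {
    reasons <- c(reasons, "insufficient_intermittent")
  }

  win_len <- window$end_min - window$start_min
  cont_ok <- TRUE
  contig_ok <- TRUE
  for (ch in c("SBP", "DBP", "MBP")) {
    s <- record$series[[series_key("continuous", ch)]]
    if (is.null(s)) { cont_ok <- FALSE; contig_ok <- FALSE; next }
    sel <- s$times >= window$start_min & s$times < window$end_min
    observed <- sum(s$valid[sel] & !s$imputed[sel])
    if (observed / win_len < cfg$min_valid_fraction) cont_ok <- FALSE
    if (is.null(longest_contiguous_window(s, window, cfg))) contig_ok <- FALSE
  }
  if (!cont_ok) reasons <- c(reasons, "insufficient_continuous")
  if (!contig_ok) reasons <- c(reasons, "no_contiguous_window")

  structure(list(patient_id = record$patient_id, window = window$label,
                 eligible = length(reasons) == 0L, reasons = reasons),
            class = "eligibility_report")
}

#' Preprocess a patient record
#'
#' Continuous channels are regularised to the 1-min grid, artefact-masked and
#' gap-imputed; intermittent channels are masked against the plausibility
#' bounds only.
#'
#' @param record A `patient_record` as loaded or simulated.
#' @param cfg A [qc_config()].
#' @return The record with processed series; attribute `qc_flags` sums the
#'   per-rule artefact counts over the continuous channels.
#' @export
preprocess_record <- function(record, cfg = qc_config()) {
  flags <- c(bounds = 0, step = 0, rolling = 0)
  for (key in names(record$series)) {
    s <- record$series[[key]]
    if (s$source == "continuous") {
      s <- average_to_minute(s)
      s <- remove_artifacts(s, cfg)
      flags <- flags + attr(s, "qc_flags")
      s <- impute_short_gaps(s, cfg)
    } else {
      b <- cfg$bounds[[s$channel]]
      s$valid <- s$valid & !is.na(s$values) & s$values >= b[1] & s$values <= b[2]
    }
    record$series[[key]] <- s
  }
  attr(record, "qc_flags") <- flags
  record
}

#' Eligibility report for a whole cohort
#'
#' @param records Named list of preprocessed `patient_record`.
#' @param windows Character vector of window labels.
#' @param cfg A [qc_config()].
#' @return Data frame: one row per patient x window with `eligible` and the
#'   pipe-separated failure `reasons` (the flow-chart accounting).
#' @export
eligibility_report <- function(records, windows = c("P1", "P2", "P3", "FULL24"),
                               cfg = qc_config()) {
  rows <- list()
  for (w in windows) {
    win <- analysis_window(w)
    for (r in records) {
      e <- assess_eligibility(r, win, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = e$patient_id, window = e$window, eligible = e$eligible,
        reasons = paste(e$reasons, collapse = "|"), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
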