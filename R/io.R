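# Long-format cohort I/O.
#
# recordings CSV: patient_id, source, channel, time_min, value_mmHg
# clinical CSV:   patient_id, nihss_category, admission_mbp,
#                 time_to_reperfusion_h, iv_thrombolysis,
#                 periprocedural_antithrombotic, ht_outcome  (booleans 0/1)

REC_COLS <- c("patient_id", "source", "channel", "time_min", "value_mmHg")
CLIN_COLS <- c("patient_id", "nihss_category", "admission_mbp",
               "time_to_reperfusion_h", "iv_thrombolysis",
               "periprocedural_antithrombotic", "ht_outcome")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Load a cohort from recordings and clinical CSV files
#'
#' Reads the long-format recordings table and the per-patient clinical table
#' and assembles `patient_record` objects. Non-numeric pressure cells are
#' loaded as invalid samples (and counted); an intermittent MBP series is
#' derived from SBP/DBP where the file does not carry one. Patients present
#' in only one of the two files are reported in the load report and excluded
#' from the analysis set rather than silently dropped.
#'
#' @param recordings_path CSV with columns
#'   `patient_id, source, channel, time_min, value_mmHg`.
#' @param clinical_path CSV with one row per patient:
#'   `patient_id, nihss_category, admission_mbp, time_to_reperfusion_h,
#'   iv_thrombolysis, periprocedural_antithrombotic, ht_outcome`.
#' @return A list with `records` (named list of `patient_record`) and
#'   `report` (patients missing from either file, count of coerced cells).
#' @export
load_cohort <- function(recordings_path, clinical_path) {
  rec <- utils::read.csv(recordings_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE)
  check_columns(rec, REC_COLS, "recordings")
  check_columns(clin, CLIN_COLS, "clinical")

  rec$time_min <- as.numeric(rec$time_min)
  if (anyNA(rec$time_min)) stop("recordings: unparsable time_min")
  key <- paste(rec$patient_id, rec$source, rec$channel, rec$time_min)
  if (anyDuplicated(key)) {
    stop("recordings: duplicate (patient, source, channel, time) rows")
  }
  vals <- suppressWarnings(as.numeric(rec$value_mmHg))
  blank <- rec$value_mmHg == "" | is.na(rec$value_mmHg)
  n_coerced <- sum(is.na(vals) & !blank)
  rec$value_mmHg <- vals

  if (anyDuplicated(clin$patient_id)) stop("clinical: duplicate patient_id")

  ids_rec <- unique(rec$patient_id)
  ids_clin <- as.character(clin$patient_id)
  common <- intersect(ids_clin, ids_rec)

  records <- lapply(common, function(id) {
    crow <- clin[ids_clin == id, , drop = FALSE]
    sub <- rec[rec$patient_id == id, , drop = FALSE]
    series <- list()
    for (src in c("continuous", "intermittent")) {
      for (ch in c("SBP", "DBP", "MBP")) {
        s <- sub[sub$source == src & sub$channel == ch, , drop = FALSE]
        if (!nrow(s)) next
        o <- order(s$time_min)
        series[[series_key(src, ch)]] <-
          bp_series(src, ch, s$time_min[o], s$value_mmHg[o])
      }
    }
    ikey <- series_key("intermittent", "MBP")
    if (is.null(series[[ikey]])) {
      sb <- series[[series_key("intermittent", "SBP")]]
      db <- series[[series_key("intermittent", "DBP")]]
      if (!is.null(sb) && !is.null(db)) {
        series[[ikey]] <- derive_intermittent_mbp(sb, db)
      }
    }
    patient_record(
      patient_id = id,
      covariates = list(
        nihss_category = as.integer(crow$nihss_category),
        admission_mbp = as.numeric(crow$admission_mbp),
        time_to_reperfusion = as.numeric(crow$time_to_reperfusion_h),
        iv_thrombolysis = as_binary(crow$iv_thrombolysis),
        periprocedural_antithrombotic = as_binary(crow$periprocedural_antithrombotic)
      ),
      ht_outcome = as_binary(crow$ht_outcome),
      series = series
    )
  })
  names(records) <- common

  list(records = records,
       report = list(
         n_patients = length(common),
         only_in_recordings = setdiff(ids_rec, ids_clin),
         only_in_clinical = setdiff(ids_clin, ids_rec),
         n_coerced_cells = n_coerced))
}

as_binary <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  out <- rep(NA, length(v))
  out[!is.na(v)] <- v[!is.na(v)] != 0
  as.logical(out)
}

# MBP derived from paired cuff readings; valid only where both inputs valid.
derive_intermittent_mbp <- function(sbp, dbp) {
  times <- sort(union(sbp$times, dbp$times))
  vs <- sbp$values[match(times, sbp$times)]
  vd <- dbp$values[match(times, dbp$times)]
  ok <- !is.na(vs) & !is.na(vd) &
    sbp$valid[match(times, sbp$times)] & dbp$valid[match(times, dbp$times)]
  ok[is.na(ok)] <- FALSE
  vals <- rep(NA_real_, length(times))
  usable <- ok & vs >= vd & vd > 0
  vals[usable] <- vs[usable] / 3 + 2 * vd[usable] / 3
  bp_series("intermittent", "MBP", times, vals)
}

#' Write a cohort back to the recordings/clinical CSV pair
#'
#' The derived intermittent MBP channel is omitted (it is reconstructed on
#' load), so a write/load round trip is lossless.
#'
#' @param records Named list of `patient_record`.
#' @param recordings_path,clinical_path Output CSV paths.
#' @export
write_cohort <- function(records, recordings_path, clinical_path) {
  rec_rows <- list()
  clin_rows <- list()
  for (r in records) {
    for (s in r$series) {
      if (s$source == "intermittent" && s$channel == "MBP") next
      keep <- !is.na(s$values)
      if (!any(keep)) next
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        patient_id = r$patient_id, source = s$source, channel = s$channel,
        time_min = s$times[keep],
        value_mmHg = sprintf("%.17g", s$values[keep]),
        stringsAsFactors = FALSE)
    }
    cv <- r$covariates
    clin_rows[[length(clin_rows) + 1L]] <- data.frame(
      patient_id = r$patient_id,
      nihss_category = cv$nihss_category,
      admission_mbp = cv$admission_mbp,
      time_to_reperfusion_h = cv$time_to_reperfusion,
      iv_thrombolysis = as.integer(cv$iv_thrombolysis),
      periprocedural_antithrombotic = as.integer(cv$periprocedural_antithrombotic),
      ht_outcome = as.integer(r$ht_outcome),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, rec_rows), recordings_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, clin_rows), clinical_path, row.names = FALSE)
  invisible(NULL)
}

#' Write an analysis table to CSV
#'
#' Numeric columns are serialised with 17 significant digits so a text round
#' trip reproduces the values bit-identically. Refuses empty input and does
#' not create a file in that case.
#'
#' @param rows A data frame (feature table, odds-ratio results, CV results,
#'   eligibility report, ...).
#' @param path Output CSV path.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows) || !nrow(rows)) stop("write_table: empty input")
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(NULL)
}

#' Read a table written by [write_table()]
#'
#' @param path CSV path.
#' @return A data frame with numeric columns restored.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
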