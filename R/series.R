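#' Blood-pressure series
#'
#' A time-stamped, validity-masked pressure series for one channel
#' (SBP/DBP/MBP) from one monitoring source (continuous finger-cuff averaged
#' to 1-min samples, or intermittent arm-cuff readings on the 15/30/60-min
#' schedule). Times are minutes since the end of reperfusion; values are in
#' mmHg. `valid` marks usable samples (`FALSE` = missing or artefact-flagged);
#' `imputed` marks samples whose value was filled by the Gaussian-filter gap
#' imputation, so downstream features can distinguish observed from imputed.
#'
#' @param source `"continuous"` or `"intermittent"`.
#' @param channel `"SBP"`, `"DBP"` or `"MBP"`.
#' @param times Numeric, minutes since end of reperfusion, strictly increasing,
#'   non-negative.
#' @param values Numeric pressures in mmHg; may be `NA` where invalid.
#' @param valid Logical mask aligned with `times`; defaults to `!is.na(values)`.
#' @param imputed Logical mask of imputed samples; defaults to all `FALSE`.
#' @return An object of class `bp_series`.
#' @export
bp_series <- function(source, channel, times, values,
                      valid = !is.na(values),
                      imputed = rep(FALSE, length(times))) {
  source <- match.arg(source, c("continuous", "intermittent"))
  channel <- match.arg(channel, c("SBP", "DBP", "MBP"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(values) != length(times) || length(valid) != length(times) ||
      length(imputed) != length(times)) {
    stop("times, values, valid and imputed must have equal length")
  }
  if (length(times) && (any(times < 0) || any(diff(times) <= 0))) {
    stop("times must be non-negative and strictly increasing")
  }
  valid <- as.logical(valid) & !is.na(values)
  structure(
    list(source = source, channel = channel, times = times,
         values = values, valid = valid, imputed = as.logical(imputed)),
    class = "bp_series"
  )
}

#' @export
print.bp_series <- function(x, ...) {
  cat(sprintf("<bp_series %s/%s: %d samples, %d valid (%d imputed)>\n",
              x$source, x$channel, length(x$times), sum(x$valid),
              sum(x$imputed)))
  invisible(x)
}

#' @export
length.bp_series <- function(x) length(x$times)

#' Mean blood pressure from systolic and diastolic pressure
#'
#' MBP = SBP/3 + 2*DBP/3, the standard weighting of one systolic and two
#' diastolic parts. Vectorised; `NA` inputs propagate.
#'
#' @param sbp Systolic pressure, mmHg.
#' @param dbp Diastolic pressure, mmHg; requires `sbp >= dbp > 0` elementwise.
#' @return Mean pressure in mmHg.
#' @examples
#' derive_mbp(120, 60)  # 80
#' @export
derive_mbp <- function(sbp, dbp) {
  ok <- !is.na(sbp) & !is.na(dbp)
  if (any(dbp[ok] <= 0)) stop("dbp must be positive")
  if (any(sbp[ok] < dbp[ok])) stop("sbp must be >= dbp")
  sbp / 3 + 2 * dbp / 3
}

#' Analysis windows over the 24-h recording
#'
#' The day after reperfusion is split into three consecutive 8-h periods
#' P1 = \[0, 480), P2 = \[480, 960), P3 = \[960, 1440) minutes, plus the
#' aggregate FULL24 = \[0, 1440). Windows are half-open so every sample
#' belongs to exactly one 8-h period.
#'
#' @param label One of `"P1"`, `"P2"`, `"P3"`, `"FULL24"`.
#' @return A list with `label`, `start_min`, `end_min` (class `analysis_window`).
#' @export
analysis_window <- function(label = c("P1", "P2", "P3", "FULL24")) {
  label <- match.arg(label)
  bounds <- switch(label,
    P1 = c(0, 480), P2 = c(480, 960), P3 = c(960, 1440), FULL24 = c(0, 1440))
  structure(list(label = label, start_min = bounds[1], end_min = bounds[2]),
            class = "analysis_window")
}

#' Scheduled intermittent cuff times
#'
#' Arm-cuff readings every 15 min for the first 2 h, every 30 min for the
#' next 6 h, then hourly for the remaining 16 h: t = 0, 15, ..., 120;
#' 150, 180, ..., 480; 540, 600, ..., 1440. The t = 1440 slot falls outside
#' the half-open 24-h day, leaving 36 in-day slots.
#'
#' @param window Optional `analysis_window`; if given, only slots with
#'   `start_min <= t < end_min` are returned.
#' @return Numeric vector of scheduled minutes.
#' @export
intermittent_schedule <- function(window = NULL) {
  slots <- c(seq(0, 120, by = 15), seq(150, 480, by = 30), seq(540, 1440, by = 60))
  slots <- slots[slots < 1440]
  if (!is.null(window)) {
    slots <- slots[slots >= window$start_min & slots < window$end_min]
  }
  slots
}

#' Categorise an admission NIHSS score
#'
#' Default bin edges follow the 0-3 / 4-14 / 15-20 / >20 convention; the
#' alternative 0-4 / 5-15 / 16-20 / >=21 edges are available via
#' `edges = c(4, 15, 20)`.
#'
#' @param score Integer NIHSS score(s), 0-42.
#' @param edges Upper inclusive bounds of the first three bins.
#' @return Integer category 1-4 (`NA` stays `NA`).
#' @export
nihss_category <- function(score, edges = c(3, 14, 20)) {
  stopifnot(length(edges) == 3, !is.unsorted(edges))
  findInterval(score, edges + 1L) + 1L
}

# patient record -------------------------------------------------------------

series_key <- function(source, channel) paste(source, channel, sep = ".")

#' Assemble one patient record
#'
#' @param patient_id Identifier string.
#' @param covariates Named list with `nihss_category` (1-4), `admission_mbp`
#'   (mmHg), `time_to_reperfusion` (h), `iv_thrombolysis` (logical),
#'   `periprocedural_antithrombotic` (logical). `NA` entries mark missing
#'   covariates.
#' @param ht_outcome Logical: radiological haemorrhagic transformation on the
#'   24-36 h follow-up imaging; `NA` if unavailable.
#' @param series List of `bp_series`, at most one per (source, channel) pair.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, covariates, ht_outcome, series) {
  keys <- vapply(series, function(s) series_key(s$source, s$channel), "")
  if (anyDuplicated(keys)) stop("duplicate (source, channel) series")
  names(series) <- keys
  structure(list(patient_id = as.character(patient_id),
                 covariates = covariates,
                 ht_outcome = as.logical(ht_outcome),
                 series = series),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: HT=%s, %d series>\n", x$patient_id,
              ifelse(is.na(x$ht_outcome), "NA", x$ht_outcome),
              length(x$series)))
  invisible(x)
}

covariate_names <- function() {
  c("nihss_category", "admission_mbp", "time_to_reperfusion",
    "iv_thrombolysis", "periprocedural_antithrombotic")
}
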