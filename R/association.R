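# Odds ratio per 1-SD shift, univariable and covariate-adjusted.

#' Odds ratio per 1-SD shift of one feature
#'
#' The feature is standardised by the analysis-set SD (complete cases for the
#' model at hand), then entered alone (univariable) or together with the five
#' adjustment covariates — NIHSS category as three indicator contrasts,
#' admission MBP, time to reperfusion, IV thrombolysis, periprocedural
#' antithrombotic use (multivariable). OR = exp(coefficient); 95% CI =
#' exp(coefficient +- 1.96 SE); two-sided Wald p-value.
#'
#' @param features A `feature_table` (or data frame with `patient_id` and
#'   feature columns).
#' @param outcome 0/1 vector aligned with the table rows.
#' @param covariates Data frame of adjustment covariates aligned with the
#'   rows (required when `adjusted`).
#' @param feature Feature column name.
#' @param adjusted Fit the covariate-adjusted model (default `FALSE`).
#' @param ridge Optional ridge penalty (default 0: maximum likelihood, with
#'   the separation fallback of [fit_logistic()]).
#' @return One-row data frame of class `or_result`: `feature`, `model`,
#'   `or`, `ci_low`, `ci_high`, `p`, `n_used`, `separation`; or `NULL` with
#'   a message when the feature is degenerate (fewer than two distinct
#'   values among complete cases).
#' @export
or_per_sd <- function(features, outcome, covariates = NULL, feature,
                      adjusted = FALSE, ridge = 0) {
  f <- features[[feature]]
  if (is.null(f)) stop("unknown feature: ", feature)
  keep <- !is.na(f) & !is.na(outcome)
  design_cov <- NULL
  if (adjusted) {
    if (is.null(covariates)) stop("adjusted model requires covariates")
    design_cov <- adjustment_design(covariates)
    keep <- keep & stats::complete.cases(design_cov)
  }
  f <- f[keep]
  y <- outcome[keep]
  if (length(unique(f)) < 2 || stats::sd(f) == 0) {
    message("or_per_sd: feature '", feature, "' is degenerate; skipped")
    return(NULL)
  }
  z <- (f - mean(f)) / stats::sd(f)
  x <- matrix(z, ncol = 1, dimnames = list(NULL, "feature_sd"))
  if (adjusted) {
    dc <- design_cov[keep, , drop = FALSE]
    dc <- dc[, apply(dc, 2, function(col) stats::sd(col) > 0), drop = FALSE]
    x <- cbind(x, dc)
  }
  fit <- suppressWarnings(fit_logistic(x, y, ridge = ridge))
  b <- fit$coef["feature_sd"]
  se <- fit$se["feature_sd"]
  out <- data.frame(feature = feature,
                    model = if (adjusted) "multivariable" else "univariable",
                    or = exp(b),
                    ci_low = exp(b - 1.96 * se),
                    ci_high = exp(b + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    n_used = length(y),
                    separation = fit$separation,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("or_result", class(out))
  out
}

#' Association scan over all features of a table
#'
#' One univariable and one multivariable OR-per-SD model per feature column.
#' Raw two-sided p-values are reported (flagging at alpha = 0.05 without
#' multiplicity adjustment, as in the source analysis); a Benjamini-Hochberg
#' column is emitted alongside, per model type, for reference.
#'
#' @param features A `feature_table`.
#' @param outcome 0/1 vector aligned with the rows.
#' @param covariates Data frame of adjustment covariates aligned with the
#'   rows.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame of class `or_result_set` (possibly zero rows): one row
#'   per feature x model with `or`, `ci_low`, `ci_high`, `p`, `p_bh`,
#'   `significant`, `n_used`.
#' @export
run_association_scan <- function(features, outcome, covariates,
                                 alpha = 0.05) {
  feat_cols <- setdiff(names(features), "patient_id")
  rows <- list()
  for (fc in feat_cols) {
    for (adj in c(FALSE, TRUE)) {
      # degenerate features or windows too small for the model are skipped,
      # never fatal
      r <- tryCatch(
        suppressMessages(
          or_per_sd(features, outcome, covariates, fc, adjusted = adj)),
        error = function(e) NULL)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) {
    out <- data.frame(feature = character(), model = character(),
                      or = numeric(), ci_low = numeric(), ci_high = numeric(),
                      p = numeric(), p_bh = numeric(), significant = logical(),
                      n_used = integer(), separation = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("or_result_set", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (mdl in unique(out$model)) {
    sel <- out$model == mdl
    out$p_bh[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$significant <- out$p < alpha
  class(out) <- c("or_result_set", class(out))
  out
}
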