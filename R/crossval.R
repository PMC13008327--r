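# Stratified cross-validated discrimination: rank AUC, average precision,
# paired fold comparison between the two monitoring sources.

#' Stratified k-fold assignment
#'
#' Folds preserve the class ratio: each class is shuffled and dealt so that
#' every fold receives floor or ceiling counts of each class, with the extra
#' members of the minority class aligned against the smaller fold totals so
#' fold sizes differ by at most one. Assignment depends only on the outcome
#' labels and the seed, never on features.
#'
#' @param y Binary outcome (0/1 or logical).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k) aligned with `y`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.integer(as.logical(y))
  n <- length(y)
  if (min(table(y)) < k) stop("stratified_folds: a class has fewer members than folds")
  set.seed(seed)
  fold_order <- sample.int(k)          # which folds receive the extras first

  counts_for <- function(n_class) {
    base <- n_class %/% k
    extra <- n_class %% k
    cnt <- rep(base, k)
    if (extra > 0) cnt[fold_order[seq_len(extra)]] <- base + 1L
    cnt
  }
  tot <- counts_for(n)
  pos <- counts_for(sum(y == 1))
  neg <- tot - pos
  if (any(neg < 0)) {                  # tiny classes: fall back to independent deal
    neg <- counts_for(sum(y == 0))
  }

  fold <- integer(n)
  fold[sample(which(y == 1))] <- rep.int(seq_len(k), pos)
  fold[sample(which(y == 0))] <- rep.int(seq_len(k), neg)
  fold
}

#' AUC-ROC by the rank method
#'
#' Equals the proportion of concordant (positive, negative) pairs, ties
#' counting one half — the Mann-Whitney statistic.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("auc_rank: need both classes")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step integration over unique score thresholds in decreasing order:
#' AP = sum over thresholds of (recall increment) x precision, with tied
#' scores processed as one block.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels.
#' @return AP in (0, 1\].
#' @export
average_precision <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  if (n1 == 0) stop("average_precision: no positives")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  grp_last <- which(!duplicated(ss, fromLast = TRUE))  # block ends (ties grouped)
  tp <- cumsum(ys)[grp_last]
  fp <- cumsum(!ys)[grp_last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' ROC and precision-recall curve points
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels.
#' @return Data frame of curve points over decreasing unique thresholds:
#'   `threshold`, `fpr`, `tpr` (recall), `precision`.
#' @export
roc_pr_points <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  last <- which(!duplicated(ss, fromLast = TRUE))
  tp <- cumsum(ys)[last]
  fp <- cumsum(!ys)[last]
  data.frame(threshold = ss[last], fpr = fp / n0, tpr = tp / n1,
             precision = tp / (tp + fp))
}

# one source's cross-validated metrics; NA feature cells are mean-imputed on
# the training fold, features standardised by training mean/sd
cv_one_source <- function(x, y, fold, ridge) {
  k <- max(fold)
  auc <- ap <- numeric(k)
  oof <- numeric(length(y))          # pooled out-of-fold scores for curves
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    xtr <- x[tr, , drop = FALSE]
    xte <- x[te, , drop = FALSE]
    mu <- colMeans(xtr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in seq_len(ncol(xtr))) {
      xtr[is.na(xtr[, j]), j] <- mu[j]
      xte[is.na(xte[, j]), j] <- mu[j]
    }
    sdv <- apply(xtr, 2, stats::sd)
    keep <- sdv > 0
    xtr <- scale(xtr[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
    xte <- scale(xte[, keep, drop = FALSE], center = mu[keep],
                 scale = sdv[keep])
    if (length(unique(y[te])) < 2) stop("cv: fold with a single class")
    fit <- fit_logistic(xtr, y[tr], ridge = ridge)
    score <- drop(cbind(1, xte) %*% fit$coef)
    oof[te] <- score
    auc[f] <- auc_rank(score, y[te])
    ap[f] <- average_precision(score, y[te])
  }
  agg <- function(v) {
    se <- stats::sd(v) / sqrt(k)
    c(mean = mean(v), lo = mean(v) - stats::qt(0.975, k - 1) * se,
      hi = mean(v) + stats::qt(0.975, k - 1) * se)
  }
  list(fold_auc = auc, fold_ap = ap, auc = agg(auc), ap = agg(ap),
       curves = roc_pr_points(oof, y))
}

#' Cross-validated comparison of continuous vs intermittent features
#'
#' Both sources use the same patients and the identical stratified fold
#' assignment. Per fold: training-set mean imputation of missing cells,
#' training-set standardisation, ridge-penalised logistic fit, scoring of
#' the held-out fold; AUC-ROC by the rank method and average precision by
#' step integration. Aggregates are fold means with t(k-1) 95% CIs; the
#' comparison is a paired two-sided t-test on the fold-wise AUC differences
#' and AP differences.
#'
#' @param features_continuous,features_intermittent Numeric feature matrices
#'   or `feature_table`s (the `patient_id` column is dropped), same row
#'   order.
#' @param outcome Binary outcome aligned with the rows.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param ridge Ridge penalty for the all-feature models (default 1 on
#'   standardised features).
#' @return List of class `cv_result`: `continuous` and `intermittent`
#'   (fold metrics + aggregates), `comparison` (paired t statistics and
#'   p-values for AUC and AP), `fold`, `k`, `seed`.
#' @export
crossval_compare <- function(features_continuous, features_intermittent,
                             outcome, k = 10L, seed = 1L, ridge = 1) {
  as_mat <- function(ft) {
    df <- as.data.frame(ft)
    df$patient_id <- NULL
    as.matrix(df)
  }
  xc <- as_mat(features_continuous)
  xi <- as_mat(features_intermittent)
  y <- as.integer(as.logical(outcome))
  stopifnot(nrow(xc) == length(y), nrow(xi) == length(y))
  fold <- stratified_folds(y, k, seed)
  rc <- cv_one_source(xc, y, fold, ridge)
  ri <- cv_one_source(xi, y, fold, ridge)
  cmp <- function(a, b) {
    d <- a - b
    if (stats::sd(d) == 0) {       # identical metrics: no evidence of a difference
      return(c(mean_diff = mean(d), t = 0, p = 1))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    c(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
      p = tt$p.value)
  }
  structure(list(continuous = rc, intermittent = ri,
                 comparison = list(auc = cmp(rc$fold_auc, ri$fold_auc),
                                   ap = cmp(rc$fold_ap, ri$fold_ap)),
                 fold = fold, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  f <- function(a) sprintf("%.3f (%.3f-%.3f)", a["mean"], a["lo"], a["hi"])
  cat("<cv_result>\n")
  cat("  continuous  : AUC", f(x$continuous$auc), " AP", f(x$continuous$ap), "\n")
  cat("  intermittent: AUC", f(x$intermittent$auc), " AP", f(x$intermittent$ap), "\n")
  cat(sprintf("  paired t: AUC p=%.4f, AP p=%.4f\n",
              x$comparison$auc["p"], x$comparison$ap["p"]))
  invisible(x)
}

#' Flatten a `cv_result` to a data frame
#'
#' @param cv A `cv_result`.
#' @return Data frame with per-fold and aggregate metrics per source.
#' @export
cv_result_table <- function(cv) {
  mk <- function(src, r) {
    data.frame(source = src, fold = c(seq_len(cv$k), NA, NA, NA),
               stat = c(rep("fold", cv$k), "mean", "ci_low", "ci_high"),
               auc = c(r$fold_auc, r$auc), ap = c(r$fold_ap, r$ap),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("continuous", cv$continuous),
               mk("intermittent", cv$intermittent))
  attr(out, "comparison") <- cv$comparison
  out
}
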