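#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood (ridge = 0) or ridge-penalised Newton fit with an
#' unpenalised intercept. Convergence when the largest coefficient change
#' drops below `tol` (default 1e-8) within `max_iter` iterations. Wald
#' standard errors come from the inverse of the (penalised) observed
#' information. Diverging coefficients signal (quasi-)complete separation;
#' the fit is flagged and refitted with `fallback_ridge` so downstream code
#' always receives finite estimates.
#'
#' @param x Design matrix (numeric, no intercept column).
#' @param y Binary outcome vector (0/1 or logical).
#' @param ridge Ridge penalty on the non-intercept coefficients (applied on
#'   the scale of `x`; standardise first for scale-free shrinkage).
#' @param tol,max_iter Convergence controls.
#' @param fallback_ridge Penalty used when separation is detected in an
#'   unpenalised fit.
#' @return List of class `logistic_fit`: `coef` (intercept first), `se`,
#'   `vcov`, `converged`, `separation`, `n_iter`, `ridge`.
#' @export
fit_logistic <- function(x, y, ridge = 0, tol = 1e-8, max_iter = 100L,
                         fallback_ridge = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (ridge == 0) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("fit_logistic: zero-variance column in design")
    if (nrow(x) <= ncol(x) + 1) stop("fit_logistic: n must exceed p")
  }

  xd <- cbind(`(Intercept)` = 1, x)
  p <- ncol(xd)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)

  irls <- function(pen_mat) {
    beta <- numeric(p)
    for (it in seq_len(max_iter)) {
      eta <- drop(xd %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      info <- crossprod(xd, xd * w) + pen_mat
      score <- crossprod(xd, y - mu) - pen_mat %*% beta
      step <- tryCatch(solve(info, score), error = function(e) NULL)
      if (is.null(step)) return(list(beta = beta, it = it, ok = FALSE))
      beta <- beta + drop(step)
      if (max(abs(step)) < tol) {
        return(list(beta = beta, it = it, ok = TRUE, info = info))
      }
      if (max(abs(beta)) > 30) {
        return(list(beta = beta, it = it, ok = FALSE))
      }
    }
    list(beta = beta, it = max_iter, ok = FALSE)
  }

  fit <- irls(pen)
  separation <- FALSE
  used_ridge <- ridge
  if (!fit$ok && ridge == 0) {
    separation <- TRUE
    warning("fit_logistic: separation or non-convergence; refitting with ridge = ",
            fallback_ridge)
    used_ridge <- fallback_ridge
    fit <- irls(diag(c(0, rep(fallback_ridge, p - 1L)), p))
  }
  if (!fit$ok) stop("fit_logistic: did not converge")

  vc <- solve(fit$info)
  structure(list(coef = stats::setNames(fit$beta, colnames(xd)),
                 se = stats::setNames(sqrt(diag(vc)), colnames(xd)),
                 vcov = vc, converged = fit$ok, separation = separation,
                 n_iter = fit$it, ridge = used_ridge),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: %d coefficients, ridge=%g%s>\n",
              length(x$coef), x$ridge,
              if (x$separation) ", separation flagged" else ""))
  print(round(cbind(coef = x$coef, se = x$se), 4))
  invisible(x)
}

# NIHSS category (reference = lowest) as indicator contrasts plus the four
# continuous/binary adjustment covariates
adjustment_design <- function(covariates) {
  nih <- factor(covariates$nihss_category, levels = 1:4)
  ind <- stats::model.matrix(~nih)[, -1, drop = FALSE]
  colnames(ind) <- paste0("nihss_cat", 2:4)
  cbind(ind,
        admission_mbp = covariates$admission_mbp,
        time_to_reperfusion = covariates$time_to_reperfusion,
        iv_thrombolysis = covariates$iv_thrombolysis,
        periprocedural_antithrombotic = covariates$periprocedural_antithrombotic)
}
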