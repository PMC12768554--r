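#' Ordinary least squares fit of a similarity vector on decade predictors
#'
#' Fits `y = b0 + b1 x1 + ... + bk xk + e` by OLS with an intercept; the
#' standard model for predicting one RSM's upper-triangle cells from the
#' matching cells of several decade RSMs.  Rank-deficient designs are
#' rejected with the collinear columns named.
#'
#' @param y numeric response vector (e.g. a behavioral RSM's upper triangle).
#' @param X numeric matrix or data.frame of predictors, one column per
#'   decade; needs `length(y) > ncol(X) + 1` rows.
#' @return a `linear_fit`: coefficients, `sigma` (ML residual scale),
#'   `loglik`, `aic` (counting intercept and residual scale among the
#'   parameters), `r_squared`, `rss`, `n`, and the underlying `lm` object.
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stopf("length(y) = %d but nrow(X) = %d", n, nrow(X))
  if (n <= ncol(X) + 1) stopf("need more rows than predictors + intercept")
  xd <- cbind(`(Intercept)` = 1, X)
  q <- qr(xd)
  if (q$rank < ncol(xd)) {
    bad <- colnames(xd)[q$pivot[(q$rank + 1):ncol(xd)]]
    stopf("rank-deficient design; collinear column(s): %s", paste(bad, collapse = ", "))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  ll <- as.numeric(stats::logLik(fit))
  structure(
    list(coefficients = stats::coef(fit), sigma = sqrt(rss / n),
         loglik = ll, aic = stats::AIC(fit),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         rss = rss, n = n,
         predictors = colnames(X), lm = fit),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear_fit: %d obs, %d predictors, R^2 = %.4f, AIC = %.2f\n",
              x$n, length(x$predictors), x$r_squared, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) object$coefficients

#' @export
logLik.linear_fit <- function(object, ...) stats::logLik(object$lm)

#' @export
residuals.linear_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
summary.linear_fit <- function(object, ...) summary(object$lm)

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) X <- X[, object$predictors, drop = FALSE]
  as.numeric(cbind(1, X) %*% object$coefficients)
}

#' Nested-model F-test
#'
#' Extra-sum-of-squares F comparing a full OLS model with a reduced model
#' nested inside it (same response, subset of predictors):
#' `F = ((RSS_r - RSS_f) / df_diff) / (RSS_f / (n - k_full - 1))`.
#' Identical models give `F = 0, p = 1`.
#'
#' @param full,reduced [fit_linear()] objects on the same response.
#' @return list with `f_stat`, `p_value`, `df1`, `df2`.
#' @export
f_test_nested <- function(full, reduced) {
  stopifnot(inherits(full, "linear_fit"), inherits(reduced, "linear_fit"))
  if (full$n != reduced$n) stopf("models were fit to different numbers of observations")
  if (!all(reduced$predictors %in% full$predictors))
    stopf("models are not nested: reduced has predictors absent from the full model")
  df1 <- length(full$predictors) - length(reduced$predictors)
  df2 <- full$n - length(full$predictors) - 1
  if (df2 <= 0) stopf("no residual degrees of freedom in the full model")
  if (df1 == 0) return(list(f_stat = 0, p_value = 1, df1 = 0L, df2 = df2))
  extra <- max(0, reduced$rss - full$rss)
  f_stat <- (extra / df1) / (full$rss / df2)
  list(f_stat = f_stat,
       p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Decade ablation of a linear similarity model
#'
#' Quantifies each decade's predictive contribution by refitting the model
#' without that decade's column and measuring what is lost.  Per ablated
#' decade, the full and reduced models are refit on each of `folds` training
#' folds; the AIC difference is taken on the training fits and the
#' log-likelihood and R-squared differences on the held-out fold (Gaussian
#' predictive density with the training ML sigma), then averaged across
#' folds.  All deltas are full minus ablated, so positive `delta_loglik` /
#' `delta_r2` and negative `delta_aic` mean the decade helped.  A nested
#' F-test on the complete data is run per decade as well; the ten tests are
#' reported with raw (uncorrected) p-values.
#'
#' @inheritParams fit_linear
#' @param folds number of cross-validation folds (default 5).
#' @param seed RNG seed controlling the fold assignment.
#' @return an `ablation_linear` data.frame: one row per ablated decade plus
#'   an all-zero `"none"` reference row, with columns `ablated`,
#'   `delta_aic`, `delta_loglik`, `delta_r2`, `f_stat`, `p_value`.
#' @export
ablate_linear <- function(y, X, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  if (!is_count(folds) || folds < 2) stopf("folds must be >= 2")
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  full_all <- fit_linear(y, X)

  heldout_metrics <- function(fit, Xte, yte) {
    pred <- predict(fit, Xte)
    ll <- sum(stats::dnorm(yte, pred, fit$sigma, log = TRUE))
    r2 <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    c(loglik = ll, r2 = r2)
  }

  rows <- lapply(colnames(X), function(d) {
    keep <- setdiff(colnames(X), d)
    per_fold <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit_f <- fit_linear(y[tr], X[tr, , drop = FALSE])
      fit_r <- fit_linear(y[tr], X[tr, keep, drop = FALSE])
      mf <- heldout_metrics(fit_f, X[!tr, , drop = FALSE], y[!tr])
      mr <- heldout_metrics(fit_r, X[!tr, keep, drop = FALSE], y[!tr])
      c(delta_aic = fit_f$aic - fit_r$aic,
        delta_loglik = mf[["loglik"]] - mr[["loglik"]],
        delta_r2 = mf[["r2"]] - mr[["r2"]])
    }, numeric(3))
    ft <- f_test_nested(full_all, fit_linear(y, X[, keep, drop = FALSE]))
    data.frame(ablated = d,
               delta_aic = mean(per_fold["delta_aic", ]),
               delta_loglik = mean(per_fold["delta_loglik", ]),
               delta_r2 = mean(per_fold["delta_r2", ]),
               f_stat = ft$f_stat, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- rbind(
    data.frame(ablated = "none", delta_aic = 0, delta_loglik = 0, delta_r2 = 0,
               f_stat = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE),
    do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("ablation_linear", "data.frame")
  out
}
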