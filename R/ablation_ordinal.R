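#' Proportional-odds model for 0-6 relatedness ratings
#'
#' Maximum-likelihood cumulative-logit fit (via [MASS::polr()]) of ordinal
#' ratings on numeric predictors, with the convention that a positive slope
#' raises the probability of higher rating categories.  Thresholds are the
#' ordered cutpoints between adjacent categories (6 cutpoints for a full 0-6
#' scale).  Failures to converge (e.g. complete separation) are not raised:
#' the returned object carries an honest `converged = FALSE` flag and
#' whatever partial estimates are available.
#'
#' @param ratings integer ratings on an ordinal scale; at least 2 distinct
#'   levels must be observed.
#' @param X numeric matrix or data.frame of predictors.
#' @return an `ordinal_fit`: `thresholds`, `betas`, `loglik`, `n`,
#'   `converged`, `levels`, plus the underlying `polr` object and model
#'   frame (used for prediction and refits).
#' @export
fit_ordinal <- function(ratings, X) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    names(X) <- paste0("x", seq_along(X))
  y <- ordered(ratings)
  if (nlevels(y) < 2) stopf("ratings have a single response level; nothing to model")
  if (nrow(X) != length(y)) stopf("ratings and X disagree on the number of rows")
  df <- data.frame(.y = y, X, check.names = FALSE)
  if (nlevels(y) == 2L) return(fit_cumlogit2(y, X, df))
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- tryCatch(MASS::polr(fml, data = df, Hess = FALSE, model = FALSE,
                             control = list(reltol = 1e-12, maxit = 500)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(
      list(thresholds = NULL, betas = NULL, loglik = NA_real_, n = nrow(df),
           converged = FALSE, levels = levels(y), message = conditionMessage(fit),
           polr = NULL, data = df),
      class = "ordinal_fit"))
  }
  structure(
    list(thresholds = fit$zeta, betas = stats::coef(fit),
         loglik = as.numeric(stats::logLik(fit)), n = nrow(df),
         converged = fit$convergence == 0, levels = levels(y),
         polr = fit, data = df),
    class = "ordinal_fit")
}

# Two-level boundary case of the cumulative-logit model, which polr does not
# cover: one cutpoint zeta with P(Y = upper) = plogis(x'beta - zeta),
# maximized by BFGS with the analytic score.  Identical to logistic
# regression with intercept -zeta, which is what makes the plain-glm oracle
# test possible.
fit_cumlogit2 <- function(y, X, df) {
  xm <- as.matrix(X)
  storage.mode(xm) <- "double"
  upper <- as.integer(y == levels(y)[2])
  k <- ncol(xm)
  nll <- function(par) {
    eta <- as.numeric(xm %*% par[-1]) - par[1]
    -sum(upper * stats::plogis(eta, log.p = TRUE) +
           (1 - upper) * stats::plogis(-eta, log.p = TRUE))
  }
  grad <- function(par) {
    eta <- as.numeric(xm %*% par[-1]) - par[1]
    r <- upper - stats::plogis(eta)
    c(sum(r), -as.numeric(crossprod(xm, r)))
  }
  opt <- stats::optim(c(stats::qlogis(mean(1 - upper)), numeric(k)), nll, grad,
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  thresholds <- stats::setNames(opt$par[1],
                                paste(levels(y), collapse = "|"))
  betas <- stats::setNames(opt$par[-1], colnames(xm))
  structure(
    list(thresholds = thresholds, betas = betas, loglik = -opt$value,
         n = nrow(df), converged = opt$convergence == 0, levels = levels(y),
         polr = NULL, data = df),
    class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("ordinal_fit (proportional odds): %d obs, %d levels%s\n",
              x$n, length(x$levels),
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$betas)) {
    cat("slopes:\n"); print(round(x$betas, 4))
    cat("thresholds:\n"); print(round(x$thresholds, 4))
  }
  invisible(x)
}

#' @export
coef.ordinal_fit <- function(object, ...) object$betas

#' @export
logLik.ordinal_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$betas) + length(object$thresholds),
            class = "logLik")
}

#' @export
#' @param newdata data.frame of predictor values.
#' @param type `"probs"` for the category-probability matrix, `"class"` for
#'   the modal category.
#' @rdname fit_ordinal
predict.ordinal_fit <- function(object, newdata, type = c("probs", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  if (!is.null(object$polr)) {
    p <- stats::predict(object$polr, newdata = newdata, type = "probs")
    if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  } else if (length(object$levels) == 2L && !is.null(object$betas)) {
    xm <- as.matrix(newdata[, names(object$betas), drop = FALSE])
    up <- stats::plogis(as.numeric(xm %*% object$betas) - object$thresholds[1])
    p <- cbind(1 - up, up)
    colnames(p) <- object$levels
  } else {
    stopf("model did not converge; no predictions available")
  }
  if (type == "probs") p else factor(object$levels[max.col(p)], levels = object$levels,
                                     ordered = TRUE)
}

# log predictive density of observed ratings under a fitted ordinal model
lpd_ordinal <- function(fit, Xnew, ynew, floor = 1e-12) {
  p <- predict(fit, Xnew, type = "probs")
  idx <- match(as.character(ynew), colnames(p))
  if (anyNA(idx)) stopf("held-out rating level unseen in training data")
  log(pmax(p[cbind(seq_len(nrow(p)), idx)], floor))
}

#' Decade ablation of the ordinal rating model via cross-validated ELPD
#'
#' Compares the full proportional-odds model against each single-predictor
#' ablation by k-fold expected log predictive density.  Fold assignment is
#' stratified by rating level so every training fold sees all categories.
#' `elpd_diff` sums, over all held-out observations, the log predictive
#' density of the ablated model minus the full model, so a useful decade
#' produces a negative difference.  The standard error is estimated from the
#' fold-wise sums (default) and also pointwise over observations
#' (`se_point`).  Mirroring the conventional rule of thumb, differences with
#' `|elpd_diff| < 4` are flagged `negligible`.
#'
#' @inheritParams fit_ordinal
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the stratified fold assignment.
#' @return an `ablation_ordinal` data.frame: one row per ablated predictor
#'   plus a zero `"none"` row, with `elpd_diff`, `se` (fold-wise),
#'   `se_point`, `negligible`.
#' @export
ablate_ordinal <- function(ratings, X, folds = 5L, seed = 1L) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    names(X) <- paste0("x", seq_along(X))
  y <- ordered(ratings)
  n <- length(y)
  if (!is_count(folds) || folds < 2) stopf("folds must be >= 2")
  fold_id <- integer(n)
  with_seed(seed, for (lev in levels(y)) {
    idx <- which(y == lev)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  })
  cols <- names(X)
  lpd_full <- numeric(n)
  lpd_abl <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit_f <- fit_ordinal(y[tr], X[tr, , drop = FALSE])
    lpd_full[!tr] <- lpd_ordinal(fit_f, X[!tr, , drop = FALSE], y[!tr])
    for (d in cols) {
      keep <- setdiff(cols, d)
      fit_r <- fit_ordinal(y[tr], X[tr, keep, drop = FALSE])
      lpd_abl[!tr, d] <- lpd_ordinal(fit_r, X[!tr, keep, drop = FALSE], y[!tr])
    }
  }
  rows <- lapply(cols, function(d) {
    pointwise <- lpd_abl[, d] - lpd_full
    fold_sums <- tapply(pointwise, fold_id, sum)
    diff <- sum(pointwise)
    se_fold <- sqrt(folds * stats::var(as.numeric(fold_sums)))
    se_point <- sqrt(n * stats::var(pointwise))
    data.frame(ablated = d, elpd_diff = diff, se = se_fold, se_point = se_point,
               negligible = abs(diff) < 4, stringsAsFactors = FALSE)
  })
  out <- rbind(
    data.frame(ablated = "none", elpd_diff = 0, se = 0, se_point = 0,
               negligible = TRUE, stringsAsFactors = FALSE),
    do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("ablation_ordinal", "data.frame")
  out
}

#' Factorial proportional-odds model of relatedness ratings
#'
#' The Study-2-style fixed-effects rating model: age group x pair type x
#' meaning change, with all interactions.  Age and meaning change are
#' effect-coded (sum contrasts, with YA and unchanged as the omitted
#' reference levels) and pair type is dummy-coded against the non-neighbor
#' reference, matching the conventional reporting for this design.  The
#' returned contrast table gives latent-scale estimated marginal means per
#' cell and pairwise differences between pair types within each age x change
#' cell (Wald intervals), computed with \pkg{emmeans}.
#'
#' @param data data.frame with the rating and factor columns.
#' @param rating_col,age_col,pair_col,change_col column names; defaults
#'   `rating`, `cohort` (levels YA/OA), `pair_type` (levels `non_neighbor`,
#'   `n1950`, `n1990`), `change_status` (levels changed/unchanged).
#' @return list with `fit` (an [fit_ordinal()]-style `ordinal_fit`), `emm`
#'   (latent-scale marginal means per cell), `contrasts` (pairwise
#'   differences), and `coefficients`.
#' @export
fit_factorial_ordinal <- function(data, rating_col = "rating", age_col = "cohort",
                                  pair_col = "pair_type",
                                  change_col = "change_status") {
  stopifnot(is.data.frame(data))
  need <- c(rating_col, age_col, pair_col, change_col)
  missing <- setdiff(need, names(data))
  if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))

  lev_or_default <- function(x, preferred) {
    obs <- unique(as.character(x))
    pref <- preferred[preferred %in% obs]
    c(pref, setdiff(obs, pref))
  }
  age <- factor(data[[age_col]], levels = lev_or_default(data[[age_col]], c("OA", "YA")))
  chg <- factor(data[[change_col]],
                levels = lev_or_default(data[[change_col]], c("changed", "unchanged")))
  pt <- factor(data[[pair_col]],
               levels = lev_or_default(data[[pair_col]],
                                       c("non_neighbor", "n1950", "n1990")))
  cells <- table(age, pt, chg)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    desc <- apply(empty, 1, function(i)
      paste(dimnames(cells)[[1]][i[1]], dimnames(cells)[[2]][i[2]],
            dimnames(cells)[[3]][i[3]], sep = ":"))
    stopf("empty design cell(s): %s", paste(desc, collapse = ", "))
  }
  y <- ordered(data[[rating_col]])
  if (nlevels(y) < 2) stopf("ratings have a single response level")
  df <- data.frame(.y = y, age = age, pair_type = pt, change = chg)
  # effect coding for age and change (reference = last level, coded -1),
  # dummy coding for pair type (reference = first level)
  stats::contrasts(df$age) <- stats::contr.sum(nlevels(age))
  stats::contrasts(df$change) <- stats::contr.sum(nlevels(chg))
  stats::contrasts(df$pair_type) <- stats::contr.treatment(levels(pt))
  fit <- MASS::polr(.y ~ age * pair_type * change, data = df, Hess = TRUE)
  rg <- emmeans::ref_grid(fit, data = df, mode = "latent")
  emm <- emmeans::emmeans(rg, ~ pair_type | age * change)
  ctr <- emmeans::contrast(emm, method = "pairwise")
  wrapped <- structure(
    list(thresholds = fit$zeta, betas = stats::coef(fit),
         loglik = as.numeric(stats::logLik(fit)), n = nrow(df),
         converged = fit$convergence == 0, levels = levels(y),
         polr = fit, data = df),
    class = "ordinal_fit")
  list(fit = wrapped,
       emm = as.data.frame(summary(emm)),
       contrasts = as.data.frame(summary(ctr, infer = TRUE)),
       coefficients = stats::coef(fit))
}
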