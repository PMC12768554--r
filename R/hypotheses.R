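#' Lifespan weighting schemes over decades
#'
#' Three hypotheses about how meanings experienced at different points of the
#' lifespan combine into a cohort's current semantic space: `"early"` weights
#' early decades most, `"uniform"` weights all experienced decades equally,
#' `"recent"` weights recent decades most.  Unnormalized weights follow
#' `base^x` with `x` counted from the favored end (the favored decade gets
#' `base^0 = 1`; any common offset cancels under normalization), and are then
#' normalized to sum to 1.
#'
#' @param hypothesis one of `"early"`, `"uniform"`, `"recent"`.
#' @param decades ordered (increasing) vector of year labels.
#' @param base decay base in (0, 1); default 0.5.
#' @return a `hypothesis_weights` object: `hypothesis`, `decades`, `weights`
#'   (normalized), `base`.
#' @export
compute_weights <- function(hypothesis = c("early", "uniform", "recent"),
                            decades, base = 0.5) {
  hypothesis <- match.arg(hypothesis)
  decades <- as.numeric(decades)
  if (!length(decades)) stopf("decades must be non-empty")
  if (is.unsorted(decades, strictly = TRUE)) stopf("decades must be strictly increasing")
  if (!is.numeric(base) || length(base) != 1 || base <= 0 || base >= 1)
    stopf("base must lie strictly in (0, 1)")
  n <- length(decades)
  raw <- switch(hypothesis,
                early   = base^(seq_len(n) - 1),
                recent  = base^(rev(seq_len(n)) - 1),
                uniform = rep(1, n))
  structure(list(hypothesis = hypothesis, decades = decades,
                 weights = raw / sum(raw), base = base),
            class = "hypothesis_weights")
}

#' @export
print.hypothesis_weights <- function(x, ...) {
  cat(sprintf("hypothesis_weights (%s, base %.2f):\n", x$hypothesis, x$base))
  print(stats::setNames(round(x$weights, 4), x$decades))
  invisible(x)
}

#' Weighted mean of decade RSMs
#'
#' Cellwise convex combination of the decade RSMs under a weighting scheme;
#' symmetry and the unit diagonal are preserved because the weights sum to 1.
#'
#' @param rsms ordered list of RSMs sharing vocabulary and order; must match
#'   `w$decades` in length.
#' @param w a [compute_weights()] object (or bare numeric weights summing
#'   to 1).
#' @return an [new_rsm()] tagged with the hypothesis label.
#' @export
weighted_mean_rsm <- function(rsms, w) {
  weights <- if (inherits(w, "hypothesis_weights")) w$weights else as.numeric(w)
  tag <- if (inherits(w, "hypothesis_weights")) w$hypothesis else "weighted mean"
  if (length(rsms) != length(weights))
    stopf("got %d RSMs but %d weights", length(rsms), length(weights))
  vocab <- rownames(rsms[[1]])
  for (r in rsms) {
    if (!identical(rownames(r), vocab))
      stopf("all RSMs must share one vocabulary ordering")
  }
  acc <- matrix(0, length(vocab), length(vocab))
  for (k in seq_along(rsms)) acc <- acc + weights[k] * unclass(as.matrix(rsms[[k]]))
  new_rsm(acc, vocab, source = tag, validate = FALSE)
}

#' Cohort exposure window
#'
#' The contiguous decades a cohort has lived through, from its birth decade
#' to the latest decade on the axis.
#'
#' @param label cohort name.
#' @param experienced_decades contiguous increasing vector of year labels.
#' @param step spacing of the decade axis (default 10); consecutive
#'   experienced decades must sit exactly one step apart.
#' @export
cohort_exposure <- function(label, experienced_decades, step = 10) {
  experienced_decades <- as.numeric(experienced_decades)
  if (!length(experienced_decades)) stopf("experienced_decades must be non-empty")
  if (is.unsorted(experienced_decades, strictly = TRUE))
    stopf("experienced_decades must be strictly increasing")
  if (length(experienced_decades) > 1) {
    if (!all(diff(experienced_decades) == step))
      stopf("experienced_decades must be contiguous (every gap equal to the %s-year step)",
            step)
  }
  structure(list(label = as.character(label),
                 experienced_decades = experienced_decades),
            class = "cohort_exposure")
}

#' Compare a behavioral RSM against the three lifespan-weighting hypotheses
#'
#' Builds the early-weighted, uniform and recent-weighted combinations of the
#' decade RSMs, correlates each with the behavioral RSM via [rsa_spearman()],
#' and reports the best-scoring hypothesis.  By default the full decade axis
#' is used for every cohort (the corpus-vs-association analysis mode); pass a
#' [cohort_exposure()] to restrict the combination to the decades that cohort
#' actually experienced (the mode used for simulation-recovery checks).  Ties
#' (within 1e-12 of the maximum) are reported explicitly, never silently
#' broken.
#'
#' @param behavior an RSM from behavioral data (association or ratings).
#' @param decade_rsms named list of decade RSMs (names are year labels, in
#'   increasing order).
#' @param exposure optional [cohort_exposure()].
#' @param base decay base for the weighting, default 0.5.
#' @return a `hypothesis_rsa` data.frame with columns `hypothesis`, `rho`,
#'   and attributes `best` (character vector; length > 1 means a tie) and
#'   `tie`.
#' @export
hypothesis_rsa <- function(behavior, decade_rsms, exposure = NULL, base = 0.5) {
  stopifnot(is.list(decade_rsms))
  if (!is.null(exposure)) {
    stopifnot(inherits(exposure, "cohort_exposure"))
    keys <- as.character(exposure$experienced_decades)
    missing <- setdiff(keys, names(decade_rsms))
    if (length(missing))
      stopf("exposure decades not on the decade axis: %s", paste(missing, collapse = ", "))
    decade_rsms <- decade_rsms[keys]
  }
  if (length(decade_rsms) < 2) stopf("need at least 2 decades")
  decades <- as.numeric(names(decade_rsms))
  rhos <- vapply(c("early", "uniform", "recent"), function(h) {
    w <- compute_weights(h, decades, base = base)
    rsa_spearman(behavior, weighted_mean_rsm(decade_rsms, w))$rho
  }, numeric(1))
  out <- data.frame(hypothesis = names(rhos), rho = unname(rhos),
                    stringsAsFactors = FALSE)
  best <- out$hypothesis[out$rho >= max(out$rho) - 1e-12]
  attr(out, "best") <- best
  attr(out, "tie") <- length(best) > 1
  class(out) <- c("hypothesis_rsa", "data.frame")
  out
}

#' @export
print.hypothesis_rsa <- function(x, ...) {
  cat("hypothesis RSA:\n")
  print(data.frame(hypothesis = x$hypothesis, rho = round(x$rho, 4)))
  best <- attr(x, "best")
  if (length(best) > 1) {
    cat(sprintf("tie between: %s\n", paste(best, collapse = ", ")))
  } else {
    cat(sprintf("best hypothesis: %s\n", best))
  }
  invisible(x)
}

#' Simulated cohort-by-decade correlation pattern
#'
#' For each cohort, builds its semantic RSM as the weighted mean of its
#' experienced decades under one hypothesis (plus optional symmetric cellwise
#' Gaussian noise), then correlates that RSM against every single-decade RSM.
#' The resulting cohort x decade matrix of Spearman rho values is the
#' schematic signature of the hypothesis: recent weighting peaks every
#' cohort's curve at the latest decade, early weighting peaks the oldest
#' cohort at its earliest experienced decade, and uniform weighting peaks in
#' mid-lifespan.
#'
#' @param decade_rsms named list of decade RSMs over the full axis.
#' @param cohorts list of [cohort_exposure()] objects.
#' @param hypothesis `"early"`, `"uniform"` or `"recent"`.
#' @param noise_sd cellwise Gaussian noise added to each cohort RSM.
#' @param seed RNG seed for the noise.
#' @param base decay base, default 0.5.
#' @return matrix of rho values, one row per cohort, one column per decade.
#' @export
simulate_hypothesis_pattern <- function(decade_rsms, cohorts, hypothesis,
                                        noise_sd = 0, seed = 1L, base = 0.5) {
  stopifnot(is.list(cohorts), all(vapply(cohorts, inherits, logical(1), "cohort_exposure")))
  decades <- as.numeric(names(decade_rsms))
  labels <- vapply(cohorts, `[[`, character(1), "label")
  out <- matrix(NA_real_, length(cohorts), length(decades),
                dimnames = list(labels, names(decade_rsms)))
  with_seed(seed, {
    for (i in seq_along(cohorts)) {
      keys <- as.character(cohorts[[i]]$experienced_decades)
      missing <- setdiff(keys, names(decade_rsms))
      if (length(missing))
        stopf("cohort '%s' experiences decades off the axis: %s",
              labels[i], paste(missing, collapse = ", "))
      w <- compute_weights(hypothesis, cohorts[[i]]$experienced_decades, base = base)
      m <- weighted_mean_rsm(decade_rsms[keys], w)
      noised <- new_rsm(add_symmetric_noise(m, noise_sd), rownames(m),
                        source = sprintf("cohort %s (%s)", labels[i], hypothesis),
                        validate = FALSE)
      out[i, ] <- vapply(decade_rsms, function(r) rsa_spearman(noised, r)$rho,
                         numeric(1))
    }
  })
  out
}
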