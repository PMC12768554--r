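#' Representational similarity analysis between two RSMs
#'
#' Correlates the off-diagonal upper triangles of two RSMs with Spearman's
#' rank correlation (average ranks for ties).  If the vocabularies differ,
#' both matrices are first restricted to the lexicographically sorted shared
#' vocabulary so that cells line up; fewer than 3 shared words (fewer than 3
#' cells) is an error.  A constant upper triangle on either side makes the
#' rank correlation undefined; the result is then flagged `degenerate` with
#' `rho = NA` rather than raising, because permutation shuffles can create
#' such cases.
#'
#' @param a,b [new_rsm()] objects (or symmetric matrices with word dimnames).
#' @param labels optional length-2 character vector naming the sources.
#' @return an `rsa_result`: list with `rho`, `n_pairs`, `labels`,
#'   `degenerate`.
#' @export
rsa_spearman <- function(a, b, labels = NULL) {
  va <- rownames(a); vb <- rownames(b)
  if (is.null(va) || is.null(vb)) stopf("both RSMs need word dimnames")
  if (!identical(va, vb)) {
    shared <- stringSort(intersect(va, vb))
    if (length(shared) < 3)
      stopf("fewer than 3 shared words (%d); RSA needs at least 3 cells", length(shared))
    a <- unclass(as.matrix(a))[shared, shared, drop = FALSE]
    b <- unclass(as.matrix(b))[shared, shared, drop = FALSE]
  }
  x <- upper_triangle_values(a)
  y <- upper_triangle_values(b)
  labels <- labels %||% c(attr(a, "source") %||% "a", attr(b, "source") %||% "b")
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  rho <- if (degenerate) NA_real_ else stats::cor(x, y, method = "spearman")
  structure(list(rho = rho, n_pairs = length(x), labels = labels,
                 degenerate = degenerate),
            class = "rsa_result")
}

#' @export
print.rsa_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("RSA (%s vs %s): degenerate (constant upper triangle), %d cells\n",
                x$labels[1], x$labels[2], x$n_pairs))
  } else {
    cat(sprintf("RSA (%s vs %s): Spearman rho = %.3f over %d cells\n",
                x$labels[1], x$labels[2], x$rho, x$n_pairs))
  }
  invisible(x)
}

#' Split-half reliability of an RSM-construction procedure
#'
#' Partitions the participants (not the records) of a behavioral dataset into
#' random halves, builds one RSM per half with the supplied builder, and
#' correlates the halves with [rsa_spearman()]; the mean over `n_splits`
#' splits estimates the internal reliability of the group's RSM and an upper
#' bound for its correlations with any other data source.  Splitting by
#' participant prevents within-participant leakage across halves.
#'
#' @param records a data.frame of association or rating records containing
#'   `participant_col`.
#' @param builder function taking a subset of `records` and returning an RSM.
#' @param n_splits number of random half-splits (5 is typical for
#'   association data, 100 for rating data).
#' @param seed RNG seed; identical seeds give identical splits.
#' @param participant_col column identifying participants.
#' @return list with `mean_rho` and the per-split `rhos`.
#' @export
split_half_reliability <- function(records, builder, n_splits = 5L, seed = 1L,
                                   participant_col = "participant_id") {
  stopifnot(is.data.frame(records), is.function(builder))
  ids <- unique(records[[participant_col]])
  if (length(ids) < 2) stopf("need at least 2 participants to split")
  rhos <- with_seed(seed, vapply(seq_len(n_splits), function(i) {
    perm <- sample(ids)
    half <- length(ids) %/% 2
    in_first <- records[[participant_col]] %in% perm[seq_len(half)]
    r1 <- builder(records[in_first, , drop = FALSE])
    r2 <- builder(records[!in_first, , drop = FALSE])
    rsa_spearman(r1, r2)$rho
  }, numeric(1)))
  list(mean_rho = mean(rhos), rhos = rhos)
}

#' Inter-annotator agreement of ordinal ratings
#'
#' For every rater, the Spearman correlation between their ratings and the
#' item-wise mean of all other raters' ratings on the items they share;
#' agreement is the average over raters.  Raters with fewer than 3 shared
#' items are skipped with a warning.  When `group_col` is given the
#' computation is repeated per group (e.g. per cohort).
#'
#' @param ratings data.frame of rating records.
#' @param rater_col,rating_col,group_col column names.
#' @param item_cols columns jointly identifying an item (default the
#'   unordered target/partner word pair).
#' @return data.frame with one row per group: `group`, `mean_rho`,
#'   `n_raters` (raters actually used).
#' @export
interannotator_agreement <- function(ratings, rater_col = "participant_id",
                                     item_cols = c("target", "partner"),
                                     rating_col = "rating", group_col = NULL) {
  stopifnot(is.data.frame(ratings))
  groups <- if (is.null(group_col)) list(all = ratings)
            else split(ratings, ratings[[group_col]])
  out <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    item <- do.call(paste, c(unname(df[item_cols]), sep = "\r"))
    rater <- as.character(df[[rater_col]])
    # rater x item matrix of mean ratings
    m <- tapply(df[[rating_col]], list(rater, item), mean)
    rhos <- c()
    for (r in rownames(m)) {
      own <- m[r, ]
      others <- m[rownames(m) != r, , drop = FALSE]
      other_mean <- colMeans(others, na.rm = TRUE)
      ok <- !is.na(own) & !is.nan(other_mean) & !is.na(other_mean)
      if (sum(ok) < 3) {
        warnf("rater '%s' skipped: fewer than 3 shared items", r)
        next
      }
      if (stats::sd(own[ok]) == 0 || stats::sd(other_mean[ok]) == 0) {
        warnf("rater '%s' skipped: constant ratings", r)
        next
      }
      rhos <- c(rhos, stats::cor(own[ok], other_mean[ok], method = "spearman"))
    }
    data.frame(group = g, mean_rho = mean(rhos), n_raters = length(rhos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Temporal-distance permutation test over decade RSMs
#'
#' Tests whether nearby decades have more similar semantic spaces than
#' distant ones.  The observed statistic is the Spearman correlation between
#' the temporal distance `|decade_i - decade_j|` and the pairwise
#' representational dissimilarity (minus the RSA value) over all decade
#' pairs, so that a similarity gradient that decays with distance yields a
#' positive `rho_obs` -- the reporting convention for distance-vs-change
#' correlations.  The null distribution is obtained by shuffling the decade
#' labels `n_perm` times and recomputing, and the central 95% interval of
#' that null is reported; a real gradient shows up as `rho_obs` outside that
#' interval.
#'
#' @param decade_rsms named list of RSMs; names are the year labels.
#' @param n_perm number of label permutations (values below 100 trigger a
#'   warning, the interval is unstable).
#' @param seed RNG seed for the permutations.
#' @return a `permutation_result`: `rho_obs`, `null_low`, `null_high`,
#'   `n_perm`, `seed`, `outside` (is `rho_obs` outside the interval) and a
#'   `degenerate` flag for constant pairwise-RSA vectors.
#' @export
temporal_permutation_test <- function(decade_rsms, n_perm = 1000L, seed = 1L) {
  stopifnot(is.list(decade_rsms))
  if (length(decade_rsms) < 3) stopf("need at least 3 decades")
  decades <- suppressWarnings(as.numeric(names(decade_rsms)))
  if (anyNA(decades)) stopf("decade_rsms must be named by numeric year labels")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (n_perm < 100) warnf("n_perm < 100: the null interval will be unstable")
  pairs <- utils::combn(length(decades), 2)
  rho_vec <- apply(pairs, 2, function(ij)
    rsa_spearman(decade_rsms[[ij[1]]], decade_rsms[[ij[2]]])$rho)
  dist_vec <- abs(decades[pairs[1, ]] - decades[pairs[2, ]])
  if (stats::sd(rho_vec) == 0) {
    return(structure(list(rho_obs = NA_real_, null_low = NA_real_,
                          null_high = NA_real_, n_perm = as.integer(n_perm),
                          seed = as.integer(seed), outside = NA,
                          degenerate = TRUE),
                     class = "permutation_result"))
  }
  rho_obs <- stats::cor(dist_vec, -rho_vec, method = "spearman")
  null <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    lab <- sample(decades)
    d <- abs(lab[pairs[1, ]] - lab[pairs[2, ]])
    if (stats::sd(d) == 0) return(NA_real_)
    stats::cor(d, -rho_vec, method = "spearman")
  }, numeric(1)))
  qs <- stats::quantile(null, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(rho_obs = rho_obs, null_low = qs[1], null_high = qs[2],
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 outside = rho_obs < qs[1] || rho_obs > qs[2],
                 degenerate = FALSE),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("temporal permutation test: degenerate (all pairwise RSA values equal)\n")
  } else {
    cat(sprintf(
      "temporal permutation test: rho_obs = %.3f, null 95%% interval [%.3f, %.3f] (%d permutations)%s\n",
      x$rho_obs, x$null_low, x$null_high, x$n_perm,
      if (x$outside) " -> outside the null interval" else ""))
  }
  invisible(x)
}

#' All pairwise RSA values between two sets of RSMs
#'
#' Convenience for the decade-by-decade, cohort-by-cohort and
#' decade-by-cohort comparison tables.
#'
#' @param rsms_a,rsms_b named lists of RSMs; `rsms_b` defaults to `rsms_a`.
#' @return matrix of Spearman rho values, rows named after `rsms_a`.
#' @export
rsa_matrix <- function(rsms_a, rsms_b = rsms_a) {
  out <- matrix(NA_real_, length(rsms_a), length(rsms_b),
                dimnames = list(names(rsms_a), names(rsms_b)))
  for (i in seq_along(rsms_a)) for (j in seq_along(rsms_b)) {
    out[i, j] <- rsa_spearman(rsms_a[[i]], rsms_b[[j]])$rho
  }
  out
}
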