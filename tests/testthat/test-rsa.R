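test_that("upper triangle extraction is row-major with the forced length", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 0                      # fill named cells explicitly
  vals <- c("12" = 1, "13" = 2, "14" = 3, "23" = 4, "24" = 5, "34" = 6)
  for (nm in names(vals)) {
    i <- as.integer(substr(nm, 1, 1)); j <- as.integer(substr(nm, 2, 2))
    m[i, j] <- vals[[nm]]; m[j, i] <- vals[[nm]]
  }
  # row-major order: (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  expect_equal(upper_triangle_values(m), c(1, 2, 3, 4, 5, 6))

  r3 <- random_rsm(3, seed = 1)
  expect_equal(upper_triangle_values(r3),
               c(r3[1, 2], r3[1, 3], r3[2, 3]), ignore_attr = TRUE)
  expect_length(upper_triangle_values(random_rsm(10, seed = 2)), 45)
  expect_length(upper_triangle_values(random_rsm(2, seed = 3)), 1)

  bad <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(upper_triangle_values(bad), "asymmetric")
})

test_that("RSA equals the rank-then-Pearson double-loop oracle", {
  a <- random_rsm(4, seed = 10)
  b <- random_rsm(4, seed = 20)
  got <- rsa_spearman(a, b)
  expect_s3_class(got, "rsa_result")
  expect_equal(got$n_pairs, 6L)
  expect_equal(got$rho,
               spearman_oracle(upper_triangle_values(a), upper_triangle_values(b)),
               tolerance = 1e-12)

  expect_equal(rsa_spearman(a, a)$rho, 1)
  # strictly decreasing transform of the cells reverses every rank
  bdec <- new_rsm(exp(-3 * unclass(a)), rownames(a), validate = FALSE)
  diag(bdec) <- 1
  expect_equal(rsa_spearman(a, bdec)$rho, -1)
})

test_that("RSA is symmetric, reorder invariant, and monotone-transform invariant", {
  for (s in 1:10) {
    a <- random_rsm(8, seed = s)
    b <- random_rsm(8, seed = s + 100)
    expect_equal(rsa_spearman(a, b)$rho, rsa_spearman(b, a)$rho, tolerance = 1e-12)
    # common relabeling of the shared vocabulary
    perm <- chronolex:::with_seed(s, sample(8))
    ap <- new_rsm(unclass(a)[perm, perm], rownames(a)[perm], validate = FALSE)
    bp <- new_rsm(unclass(b)[perm, perm], rownames(b)[perm], validate = FALSE)
    expect_equal(rsa_spearman(ap, bp)$rho, rsa_spearman(a, b)$rho, tolerance = 1e-12)
    # strictly monotone transform of either side's cells
    bt <- new_rsm(tanh(2 * unclass(b)) + 0.1 * unclass(b), rownames(b), validate = FALSE)
    expect_equal(rsa_spearman(a, bt)$rho, rsa_spearman(a, b)$rho, tolerance = 1e-12)
  }
  # mismatched vocabularies are intersected; too small an overlap errors
  a <- random_rsm(5, seed = 1)
  small <- new_rsm(diag(2), c("w01", "w02"), validate = FALSE)
  expect_error(rsa_spearman(a, small), "3")
})

test_that("degenerate constant triangles are flagged, not raised", {
  const <- new_rsm(matrix(1, 4, 4), sprintf("w%02d", 1:4), validate = FALSE)
  r <- rsa_spearman(const, random_rsm(4, seed = 5))
  expect_true(r$degenerate)
  expect_true(is.na(r$rho))
})

test_that("split-half reliability is 1 for duplicated deterministic raters", {
  # every participant carries an identical copy of one rating pattern
  pairs <- expand.grid(target = c("a", "b", "c", "d"), partner = c("e", "f"),
                       stringsAsFactors = FALSE)
  base_rating <- seq_len(nrow(pairs))
  rec <- do.call(rbind, lapply(sprintf("p%02d", 1:8), function(p)
    data.frame(participant_id = p, pairs, rating = base_rating)))
  builder <- function(df) {
    words <- sort(unique(c(df$target, df$partner)))
    m <- matrix(0, length(words), length(words), dimnames = list(words, words))
    agg <- aggregate(rating ~ target + partner, df, mean)
    for (k in seq_len(nrow(agg))) {
      m[agg$target[k], agg$partner[k]] <- agg$rating[k]
      m[agg$partner[k], agg$target[k]] <- agg$rating[k]
    }
    diag(m) <- 1
    new_rsm(m, words, source = "ratings", validate = FALSE)
  }
  out <- split_half_reliability(rec, builder, n_splits = 4, seed = 9)
  expect_equal(out$rhos, rep(1, 4))

  # reproducibility from the seed
  out2 <- split_half_reliability(rec, builder, n_splits = 4, seed = 9)
  expect_identical(out, out2)
})

test_that("split-half reliability of pure noise is near zero", {
  set.seed(77)
  pairs <- expand.grid(target = sprintf("t%02d", 1:12), partner = c("x", "y", "z"),
                       stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(sprintf("p%02d", 1:40), function(p)
    data.frame(participant_id = p, pairs, rating = rnorm(nrow(pairs)))))
  builder <- function(df) {
    words <- sort(unique(c(df$target, df$partner)))
    m <- matrix(0, length(words), length(words), dimnames = list(words, words))
    agg <- aggregate(rating ~ target + partner, df, mean)
    m[cbind(agg$target, agg$partner)] <- agg$rating
    m[cbind(agg$partner, agg$target)] <- agg$rating
    diag(m) <- 1
    new_rsm(m, words, validate = FALSE)
  }
  out <- split_half_reliability(rec, builder, n_splits = 30, seed = 5)
  expect_lt(abs(out$mean_rho), 0.05)
})

test_that("inter-annotator agreement matches hand computations", {
  items <- data.frame(target = c("a", "b", "c"), partner = "z")
  identical_raters <- do.call(rbind, lapply(c("r1", "r2", "r3"), function(r)
    data.frame(participant_id = r, items, rating = c(1, 4, 6))))
  out <- interannotator_agreement(identical_raters)
  expect_equal(out$mean_rho, 1)

  # one reversed rater on a 3-item set contributes exactly -1
  rev_rater <- rbind(
    do.call(rbind, lapply(c("r1", "r2"), function(r)
      data.frame(participant_id = r, items, rating = c(1, 4, 6)))),
    data.frame(participant_id = "r3", items, rating = c(6, 4, 1)))
  out <- interannotator_agreement(rev_rater)
  # r1, r2 agree with the others' means imperfectly; recompute by hand
  m <- rbind(c(1, 4, 6), c(1, 4, 6), c(6, 4, 1))
  rhos <- sapply(1:3, function(i)
    spearman_oracle(m[i, ], colMeans(m[-i, , drop = FALSE])))
  expect_equal(out$mean_rho, mean(rhos), tolerance = 1e-12)
  expect_equal(rhos[3], -1)

  # independent random raters over many items average out near zero
  set.seed(12)
  many <- expand.grid(target = sprintf("t%03d", 1:150), partner = "z",
                      stringsAsFactors = FALSE)
  noisy <- do.call(rbind, lapply(sprintf("r%02d", 1:12), function(r)
    data.frame(participant_id = r, many, rating = sample(0:6, nrow(many), TRUE))))
  out <- interannotator_agreement(noisy)
  expect_lt(abs(out$mean_rho), 0.05)

  # raters with fewer than 3 shared items are skipped with a warning
  sparse <- rbind(identical_raters,
                  data.frame(participant_id = "r9",
                             target = "a", partner = "z", rating = 3))
  expect_warning(out <- interannotator_agreement(sparse), "r9")
  expect_equal(out$n_raters, 3L)
})

test_that("temporal permutation test detects a planted distance gradient", {
  # decade t's upper-triangle cells are the cyclic shift by 3t of 1..45, so
  # Spearman between decades at lag k is exactly 1 - 6s(45 - s)/(45^2 - 1)
  # with s = 3k: strictly decreasing similarity with temporal distance
  v <- 10
  K <- v * (v - 1) / 2
  decades <- seq(1940, 1990, 10)
  vocab <- sprintf("w%02d", seq_len(v))
  rsms <- lapply(seq_along(decades), function(i) {
    cells <- ((seq_len(K) - 1 + 3 * (i - 1)) %% K) + 1
    m <- matrix(0, v, v)
    tm <- t(m); tm[lower.tri(tm)] <- cells; m <- t(tm)   # row-major fill
    m <- m + t(m); diag(m) <- 1
    new_rsm(m, vocab, validate = FALSE)
  })
  names(rsms) <- decades
  # the planted pairwise similarity at lag 2 (shift s = 6) is exactly the
  # closed-form rank correlation of a cyclic shift: 1 - 6 s (K - s) / (K^2 - 1)
  expect_equal(rsa_spearman(rsms[[1]], rsms[[3]])$rho,
               1 - 6 * 6 * (K - 6) / (K^2 - 1), tolerance = 1e-12)
  res <- temporal_permutation_test(rsms, n_perm = 1000, seed = 8)
  expect_equal(res$rho_obs, 1)         # dissimilarity rises strictly with lag
  expect_true(res$outside)
  expect_lte(res$null_low, res$null_high)

  # identical RSMs at all decades: constant rho vector, degenerate flag
  same <- stats::setNames(rep(rsms[1], 4), seq(1900, 1930, 10))
  deg <- temporal_permutation_test(same, n_perm = 200, seed = 1)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho_obs))

  expect_warning(temporal_permutation_test(rsms, n_perm = 50, seed = 1), "unstable")
  expect_error(temporal_permutation_test(rsms[1:2], n_perm = 200), "3 decades")
})

test_that("rsa_matrix lays out all pairwise comparisons", {
  rsms <- stats::setNames(lapply(1:3, function(i) random_rsm(6, seed = i)),
                          c("1950", "1970", "1990"))
  m <- rsa_matrix(rsms)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(diag(m), rep(1, 3), ignore_attr = TRUE)
  expect_equal(m["1950", "1990"], rsa_spearman(rsms[[1]], rsms[[3]])$rho)
  expect_equal(m, t(m))
})
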