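# Independent oracles and fixture builders.  These deliberately avoid the
# package's own code paths: ranks are computed by counting, the walk by
# explicit series summation, Procrustes by a from-scratch closed form.

# average ranks by pairwise counting (no rank())
rank_by_counting <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    smaller <- sum(x < x[i])
    ties <- sum(x == x[i])
    out[i] <- smaller + (ties + 1) / 2
  }
  out
}

# Spearman rho: rank by counting, then the explicit Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank_by_counting(x)
  ry <- rank_by_counting(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# truncated Katz series sum_{k=0..kmax} alpha^k P^k
katz_series_oracle <- function(P, alpha, kmax = 50) {
  acc <- diag(nrow(P))
  term <- diag(nrow(P))
  for (k in seq_len(kmax)) {
    term <- alpha * (term %*% P)
    acc <- acc + term
  }
  acc
}

# independent orthogonal-Procrustes solution: rotation and residual from a
# from-scratch SVD of X'Y
procrustes_oracle <- function(X, Y) {
  s <- svd(t(X) %*% Y)
  R <- s$u %*% t(s$v)
  list(rotation = R, residual = sqrt(sum((X %*% R - Y)^2)))
}

# random orthogonal matrix via QR with a sign fix
random_orthogonal <- function(d) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  q %*% diag(sign(diag(q)[1]) * rep(1, d))
}

# random symmetric RSM with unit diagonal over letter vocabulary
random_rsm <- function(v, seed = NULL, source = "test") {
  gen <- function() {
    m <- matrix(runif(v * v, -1, 1), v)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  }
  m <- if (is.null(seed)) gen() else chronolex:::with_seed(seed, gen())
  vocab <- sprintf("w%02d", seq_len(v))
  new_rsm(m, vocab, source = source, validate = FALSE)
}

# tiny two-decade aligned series with hand-planted cross-decade angles:
# word i's decade-2 vector is its decade-1 vector rotated by angles[i]
planted_angle_series <- function(angles, t1 = 1950, t2 = 1990) {
  n <- length(angles)
  words <- sprintf("w%02d", seq_len(n))
  # embed each word in its own 2-D plane of a 2n-dim space
  d <- 2 * n
  v1 <- matrix(0, n, d)
  v2 <- matrix(0, n, d)
  for (i in seq_len(n)) {
    v1[i, 2 * i - 1] <- 1
    v2[i, 2 * i - 1] <- cos(angles[i])
    v2[i, 2 * i] <- sin(angles[i])
  }
  aligned_series(list(decade_embeddings(t1, words, v1),
                      decade_embeddings(t2, words, v2)),
                 aligned = TRUE, reference_decade = t2)
}

# small deterministic association record table
make_assoc_records <- function(participants, cues, responses, ages = NULL,
                               position = NULL) {
  n <- max(length(participants), length(cues), length(responses))
  data.frame(participant_id = rep_len(participants, n),
             age = rep_len(ages %||% 30, n),
             cue = rep_len(cues, n),
             response = rep_len(responses, n),
             position = rep_len(position %||% 1L, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical small simulated series shared by several tests (cached per run)
small_series <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_diachronic_embeddings(
        drift_config(n_words = 60, dim = 30, n_decades = 6,
                     first_decade = 1940, n_changed = 20, seed = 42))
    cache
  }
})
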