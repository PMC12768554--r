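test_that("generators are pure functions of config and seed", {
  cfg <- drift_config(n_words = 40, dim = 20, n_decades = 4, seed = 9)
  s1 <- simulate_diachronic_embeddings(cfg)
  s2 <- simulate_diachronic_embeddings(cfg)
  expect_identical(s1$decades[["1930"]]$vectors, s2$decades[["1930"]]$vectors)
  expect_identical(attr(s1, "ground_truth"), attr(s2, "ground_truth"))

  r <- cosine_rsm(s1$decades[["1930"]])
  rec1 <- simulate_association_responses(r, cfg = response_sim_config(9, seed = 4))
  rec2 <- simulate_association_responses(r, cfg = response_sim_config(9, seed = 4))
  expect_identical(rec1, rec2)

  pairs <- data.frame(target = rownames(r)[1:5], partner = rownames(r)[6:10])
  rat1 <- simulate_ratings(r, pairs, rating_sim_config(seed = 3), "OA")
  rat2 <- simulate_ratings(r, pairs, rating_sim_config(seed = 3), "OA")
  expect_identical(rat1, rat2)
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_diachronic_embeddings(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a zero-drift config reproduces identical decades", {
  cfg <- drift_config(n_words = 25, dim = 10, n_decades = 5, n_changed = 0,
                      base_drift_sd = 0, decade_noise_sd = 0,
                      adjacent_rsm_cor = NULL, seed = 2)
  s <- simulate_diachronic_embeddings(cfg)
  for (key in names(s$decades)[-1])
    expect_equal(s$decades[[key]]$vectors, s$decades[[1]]$vectors, tolerance = 1e-12)
  rs <- decade_rsms(s)
  expect_equal(rsa_spearman(rs[[1]], rs[[5]])$rho, 1)
})

test_that("generated series obeys the embedding-module invariants", {
  s <- small_series()
  expect_true(s$aligned)
  vocab <- s$decades[[1]]$vocabulary
  expect_false(anyDuplicated(vocab) > 0)
  for (e in s$decades) {
    expect_identical(e$vocabulary, vocab)
    expect_equal(nrow(e$vectors), length(vocab))
    # unit rows by construction
    expect_equal(sqrt(rowSums(e$vectors^2)), rep(1, length(vocab)),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(self_similarity(s, vocab[1], e$decade, e$decade), 1)
  }
  gt <- attr(s, "ground_truth")
  expect_length(gt$changed, 20)
  expect_true(all(gt$changed %in% vocab))
})

test_that("drift calibration hits both self-cosine anchors", {
  s <- simulate_diachronic_embeddings(drift_config(n_words = 300, seed = 21))
  gt <- attr(s, "ground_truth")
  cls <- classify_change(s, t1 = 1900, t2 = 1990, threshold = 0.35)
  changed <- cls$self_sim[cls$word %in% gt$changed]
  stable <- cls$self_sim[!cls$word %in% gt$changed]
  expect_lt(abs(mean(changed) - 0.21), 0.05)
  expect_lt(abs(mean(stable) - 0.71), 0.05)
  # the two classes are largely separated around the threshold (the changed
  # class sits ~1.5 sd below it, so a small tail crosses)
  expect_gt(mean(changed < 0.35), 0.85)
  expect_gt(mean(stable > 0.35), 0.95)
})

test_that("infeasible drift targets are rejected", {
  expect_error(
    simulate_diachronic_embeddings(
      drift_config(n_words = 20, dim = 10, n_decades = 4,
                   change_target_sim = 0.93, stable_target_sim = 0.95, seed = 1)),
    "infeasible|reachable")
  expect_error(drift_config(change_target_sim = 0.8, stable_target_sim = 0.7),
               "below")
})

test_that("cohort RSM simulation reduces to its single components", {
  s <- small_series()
  # single experienced decade, zero noise: exactly that decade's RSM
  cfg <- cohort_sim_config("one", 1960, hypothesis = "recent", rsm_noise_sd = 0)
  r <- simulate_cohort_rsm(s, cfg)
  expect_equal(unclass(r), unclass(cosine_rsm(s$decades[["1960"]])),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(r, "hypothesis"), "recent")
  # recent weighting, zero noise: RSA peaks at the latest experienced decade
  cfg2 <- cohort_sim_config("all", as.numeric(names(s$decades)),
                            hypothesis = "recent", rsm_noise_sd = 0)
  r2 <- simulate_cohort_rsm(s, cfg2)
  rhos <- vapply(decade_rsms(s), function(d) rsa_spearman(r2, d)$rho, numeric(1))
  expect_equal(which.max(rhos), length(rhos), ignore_attr = TRUE)
})

test_that("association responses are triples of distinct in-vocabulary words", {
  s <- small_series()
  r <- cosine_rsm(s$decades[["1990"]])
  rec <- simulate_association_responses(r, cues = rownames(r)[1:10],
                                        cfg = response_sim_config(15, seed = 6))
  expect_equal(sort(unique(rec$position)), 1:3)
  expect_true(all(rec$response %in% rownames(r)))
  expect_false(any(rec$response == rec$cue))
  by_pc <- split(rec$response, paste(rec$participant_id, rec$cue))
  expect_true(all(vapply(by_pc, function(x) length(unique(x)) == 3, logical(1))))
  # ~responses_per_cue records arrive per cue
  expect_true(all(table(rec$cue) == 15))
  # ages live inside the cohort window
  expect_true(all(rec$age >= 20 & rec$age < 35))
})

test_that("a near-zero temperature concentrates on the top partners", {
  s <- small_series()
  r <- cosine_rsm(s$decades[["1990"]])
  cue <- rownames(r)[1]
  top3 <- names(sort(unclass(r)[cue, -1], decreasing = TRUE))[1:3]
  rec <- simulate_association_responses(
    r, cues = cue, cfg = response_sim_config(3, temperature = 1e-4, seed = 2))
  expect_equal(rec$response[rec$position == 1], top3[1])
  expect_setequal(rec$response, top3)
})

test_that("ratings follow the latent thresholds and close the ordinal loop", {
  # hand-built RSM with an exactly minimal-similarity pair
  m <- diag(2); m[1, 2] <- m[2, 1] <- -1
  r <- new_rsm(m, c("a", "b"), validate = FALSE)
  pairs <- data.frame(target = "a", partner = "b")
  cfg <- rating_sim_config(latent_noise_sd = 0, raters_per_pair_per_cohort = 3,
                           seed = 1)
  rec <- simulate_ratings(r, pairs, cfg, "YA")
  expect_equal(rec$rating, rep(0L, 3))           # latent -6 under all cutpoints
  expect_true(all(rec$age >= 18 & rec$age <= 33))
  expect_true(all(rec$catch_score == 5 & rec$duration > 4))

  # planted quality violators are produced for the hygiene filters
  rec_v <- simulate_ratings(r, pairs, cfg, "YA", n_violators = 4)
  bad <- rec_v[!(rec_v$catch_score == 5 & rec_v$duration > 4), ]
  expect_equal(length(unique(bad$participant_id)), 4L)
  expect_equal(nrow(clean_ratings(rec_v)), 3L)

  # ordinal fit on generated ratings recovers the planted slope
  s <- small_series()
  rbig <- cosine_rsm(s$decades[["1990"]])
  vocab <- rownames(rbig)
  allp <- expand.grid(target = vocab[1:30], partner = vocab[31:60],
                      stringsAsFactors = FALSE)
  cfg2 <- rating_sim_config(latent_scale = 4, latent_noise_sd = 1,
                            raters_per_pair_per_cohort = 8, seed = 12)
  rec2 <- simulate_ratings(rbig, allp, cfg2, "OA")
  sim <- unclass(rbig)[cbind(rec2$target, rec2$partner)]
  fit <- fit_ordinal(rec2$rating, data.frame(sim = sim))
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["sim"]] - 4), 0.3)
})
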