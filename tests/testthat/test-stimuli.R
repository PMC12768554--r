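test_that("change classification follows the strict threshold rule", {
  s <- planted_angle_series(c(acos(0.21), acos(0.71), acos(0.35), acos(0.9)))
  # a word sitting exactly at the threshold is unassigned and excluded:
  # probe w03's realized self-cosine and use it as the cutoff
  boundary <- self_similarity(s, "w03", 1950, 1990)
  expect_warning(cls <- classify_change(s, threshold = boundary), "threshold")
  expect_equal(cls$change_status[cls$word == "w01"], "changed")    # 0.21
  expect_equal(cls$change_status[cls$word == "w02"], "unchanged")  # 0.71
  expect_false("w03" %in% cls$word)                                # at the cutoff
  expect_equal(cls$change_status[cls$word == "w04"], "unchanged")
  expect_equal(cls$self_sim[cls$word == "w01"], 0.21, tolerance = 1e-8)
  expect_error(classify_change(s, t1 = 1950, t2 = 1960), "1960")
})

test_that("nearest neighbors match the exhaustive-scan oracle and break ties lexically", {
  # planted duplicate ranks first with similarity 1
  words <- c("query", "clone", "far", "mid")
  v <- rbind(c(1, 0), c(2, 0), c(-1, 0.2), c(1, 1))
  emb <- decade_embeddings(1990, words, v)
  expect_equal(nearest_neighbors(emb, "query", 3), c("clone", "mid", "far"))

  # 6-word toy space vs brute-force sort
  set.seed(70)
  words6 <- c("alpha", "bravo", "carol", "delta", "echo", "fox")
  m <- matrix(rnorm(6 * 4), 6)
  emb6 <- decade_embeddings(1990, words6, m)
  mn <- m / sqrt(rowSums(m^2))
  sims <- as.numeric(mn %*% mn["alpha" == words6, ])
  oracle <- words6[-1][order(-sims[-1])]
  expect_equal(nearest_neighbors(emb6, "alpha", 5), oracle)

  # exact ties resolve lexicographically, stable across runs
  wt <- c("zz", "aa", "bb", "base")
  vt <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0.9, 0.1))
  et <- decade_embeddings(1990, wt, vt)
  expect_equal(nearest_neighbors(et, "base", 3)[1:2], c("aa", "bb"))
  expect_identical(nearest_neighbors(et, "base", 3), nearest_neighbors(et, "base", 3))

  expect_error(nearest_neighbors(emb6, "alpha", 6), "only 5")
  expect_error(nearest_neighbors(emb6, "nope", 2), "nope")
})

test_that("non-neighbor sampling stays in the complement and is seeded", {
  vocab <- sprintf("w%03d", 1:40)
  excluded <- vocab[2:15]
  for (seed in 1:50) {
    got <- sample_non_neighbors(vocab, "w001", excluded, k = 10, seed = seed)
    expect_length(got, 10)
    expect_length(intersect(got, c(excluded, "w001")), 0)
  }
  expect_identical(sample_non_neighbors(vocab, "w001", excluded, 10, seed = 7),
                   sample_non_neighbors(vocab, "w001", excluded, 10, seed = 7))
  # complement of exactly k returns the whole complement
  all_but <- setdiff(vocab, c("w001", vocab[2:31]))
  expect_setequal(sample_non_neighbors(vocab, "w001", vocab[2:31], 9, seed = 1),
                  all_but)
  expect_error(sample_non_neighbors(vocab, "w001", vocab[2:39], 5, seed = 1),
               "complement")
})

test_that("stimulus build yields the forced per-target pair inventory", {
  series <- small_series()
  pairs <- build_stimulus_pairs(series, t1 = 1940, t2 = 1990, threshold = 0.35,
                                n_changed = 10, n_unchanged = 10,
                                k_neighbors = 5, k_non = 5, seed = 3)
  expect_equal(nrow(pairs), 20 * 15)
  counts <- table(pairs$target, pairs$pair_type)
  expect_true(all(counts == 5))
  expect_setequal(colnames(counts), c("n1940", "n1990", "non_neighbor"))
  expect_equal(sum(table(unique(pairs[c("target", "change_status")])$change_status)),
               20)
  # partners never equal their target
  expect_false(any(pairs$target == pairs$partner))
  # changed targets are the lowest self-similarity words
  cls <- classify_change(series, t1 = 1940, t2 = 1990)
  changed_sims <- sort(cls$self_sim[cls$change_status == "changed"])
  expect_setequal(unique(pairs$self_sim[pairs$change_status == "changed"]),
                  changed_sims[1:10])
})

test_that("counterbalance lists satisfy the size, quota and coverage audit", {
  series <- small_series()
  pairs <- build_stimulus_pairs(series, t1 = 1940, t2 = 1990,
                                n_changed = 10, n_unchanged = 10,
                                k_neighbors = 3, k_non = 3, seed = 3)
  # 20 targets, 4 per list -> 5 lists per round; 3 pairs/type needs >= 3 rounds
  lists <- build_counterbalance_lists(pairs, n_lists = 15, targets_per_list = 4,
                                      seed = 5)
  by_list <- split(lists, lists$list_id)
  expect_length(by_list, 15)
  for (l in by_list) {
    expect_equal(nrow(l), 12)                       # 4 targets x 3 types
    expect_equal(length(unique(l$target)), 4L)
    ch <- sum(unique(l[c("target", "change_status")])$change_status == "changed")
    expect_true(ch %in% c(2L))                      # 10 changed over 5 lists
    expect_true(all(table(l$target, l$pair_type) == 1))
  }
  # coverage: every pair of every target appears in at least one list
  key_all <- unique(paste(pairs$target, pairs$partner, pairs$pair_type))
  key_used <- unique(paste(lists$target, lists$partner, lists$pair_type))
  expect_setequal(key_used, key_all)
  # deterministic under the seed
  expect_identical(lists, build_counterbalance_lists(pairs, 15, 4, seed = 5))
  expect_error(build_counterbalance_lists(pairs, n_lists = 10, targets_per_list = 4),
               "coverage")
})

test_that("uneven changed/unchanged splits alternate the 12-or-13 quota", {
  # 10 changed + 15 unchanged targets in lists of 5 -> quotas of 2 or 3
  series <- small_series()
  pairs <- build_stimulus_pairs(series, t1 = 1940, t2 = 1990,
                                n_changed = 10, n_unchanged = 15,
                                k_neighbors = 2, k_non = 2, seed = 4)
  lists <- build_counterbalance_lists(pairs, n_lists = 10, targets_per_list = 5,
                                      seed = 6)
  quotas <- sapply(split(lists, lists$list_id), function(l)
    sum(unique(l[c("target", "change_status")])$change_status == "changed"))
  expect_true(all(quotas %in% c(2L, 3L)))
  expect_equal(sum(quotas), 10 * 2)   # each changed target once per round
})

test_that("rating hygiene filters match the strict bounds", {
  rec <- data.frame(participant_id = c("a", "a", "b", "c", "d"),
                    catch_score = c(5, 5, 4, 5, 5),
                    duration = c(10, 10, 12, 4, 4.01),
                    rating = 1:5)
  out <- clean_ratings(rec)
  expect_equal(out$participant_id, c("a", "a", "d"))
  excl <- attr(out, "exclusions")
  expect_equal(unname(excl["participants_catch"]), 1)
  expect_equal(unname(excl["participants_duration"]), 1)   # exactly 4.0 is out
  expect_equal(unname(excl["records_removed"]), 2)
  # all-pass input is untouched
  ok <- rec[rec$participant_id %in% c("a", "d"), ]
  expect_equal(nrow(clean_ratings(ok)), nrow(ok))
})

test_that("duplicate unordered pairs collapse onto the first-listed type", {
  pairs <- data.frame(target = c("t", "t", "t"),
                      partner = c("shared", "other", "shared"),
                      pair_type = c("n1950", "n1950", "n1990"),
                      stringsAsFactors = FALSE)
  out <- dedupe_pairs(pairs)
  expect_equal(nrow(out), 2)
  expect_equal(out$pair_type[out$partner == "shared"], "n1950")

  # no shared neighbors: identity
  disjoint <- data.frame(target = "t", partner = c("a", "b"),
                         pair_type = c("n1950", "n1990"))
  expect_equal(dedupe_pairs(disjoint), disjoint)

  # known 10% overlap vs an enumeration oracle
  set.seed(80)
  targets <- sprintf("t%02d", 1:20)
  build <- do.call(rbind, lapply(targets, function(tw) {
    nb1 <- sprintf("%s_a%d", tw, 1:10)
    nb2 <- c(nb1[1], sprintf("%s_b%d", tw, 2:10))   # exactly 1 of 10 shared
    data.frame(target = tw, partner = c(nb1, nb2),
               pair_type = rep(c("n1950", "n1990"), each = 10))
  }))
  out <- dedupe_pairs(build)
  expect_equal(nrow(out), nrow(build) - 20)         # one duplicate per target
  # rating records: repeat ratings of the collapsed pair are reduced per rater
  recs <- rbind(data.frame(participant_id = "p1", build),
                data.frame(participant_id = "p2", build))
  out2 <- dedupe_pairs(recs)
  expect_equal(nrow(out2), 2 * (nrow(build) - 20))
})

test_that("subsampling equalizes ratings per pair and cohort", {
  set.seed(81)
  base <- expand.grid(target = c("t1", "t2", "t3"), partner = "p",
                      cohort = c("YA", "OA"), stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    n <- c(5, 8, 6)[match(base$target[i], c("t1", "t2", "t3"))]
    data.frame(base[rep(i, n), ], participant_id = sprintf("r%d", 1:n),
               rating = sample(0:6, n, TRUE))
  }))
  out <- subsample_ratings(rec, per_cohort = 5, seed = 9)
  expect_equal(nrow(out), 5 * 2 * 3)                # 10 x number of pairs
  expect_true(all(table(out$target, out$cohort) == 5))
  # exact-count groups are retained whole
  t1_ya <- out[out$target == "t1" & out$cohort == "YA", ]
  expect_setequal(t1_ya$participant_id, sprintf("r%d", 1:5))
  expect_identical(out, subsample_ratings(rec, per_cohort = 5, seed = 9))

  short <- rec[!(rec$target == "t1" & rec$cohort == "OA" &
                   rec$participant_id %in% c("r4", "r5")), ]
  expect_error(subsample_ratings(short, per_cohort = 5, seed = 1), "fewer")
  dropped <- subsample_ratings(short, per_cohort = 5, seed = 1, on_short = "drop")
  expect_false("t1" %in% dropped$target)
  expect_equal(nrow(dropped), 5 * 2 * 2)
})
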