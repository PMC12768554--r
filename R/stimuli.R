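#' Classify words as changed or unchanged in meaning
#'
#' Compares each word's aligned vectors between two decades and classifies by
#' the cross-decade self-cosine: below the threshold the word's meaning is
#' taken to have changed, above it not.  Words sitting exactly at the
#' threshold are left unassigned (the classification uses strict
#' inequalities) and excluded with a warning.
#'
#' @param series an aligned [aligned_series()] covering `t1` and `t2`.
#' @param words words to classify; default the full shared vocabulary.
#' @param t1,t2 the two decades to compare (defaults 1950 and 1990).
#' @param threshold self-cosine cutoff, default 0.35.
#' @return data.frame with `word`, `self_sim`, `change_status`
#'   (`"changed"` / `"unchanged"`).
#' @export
classify_change <- function(series, words = NULL, t1 = 1950, t2 = 1990,
                            threshold = 0.35) {
  stopifnot(inherits(series, "aligned_series"))
  if (!series$aligned) stopf("series is not aligned; align first (see align_series())")
  e1 <- get_decade(series, t1)
  words <- words %||% e1$vocabulary
  sims <- vapply(words, function(w) self_similarity(series, w, t1, t2), numeric(1))
  status <- ifelse(sims < threshold, "changed",
                   ifelse(sims > threshold, "unchanged", NA_character_))
  if (anyNA(status)) {
    warnf("%d word(s) exactly at the %.2f threshold left unassigned and excluded",
          sum(is.na(status)), threshold)
  }
  out <- data.frame(word = words, self_sim = unname(sims), change_status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!is.na(out$change_status), , drop = FALSE]
}

#' Nearest neighbors of a word within one decade
#'
#' Top-`k` vocabulary words by cosine similarity to the query word, excluding
#' the word itself.  Exact similarity ties are broken lexicographically so
#' the list is deterministic across runs.
#'
#' @param emb a [decade_embeddings()] object.
#' @param word query word (must be in the vocabulary).
#' @param k number of neighbors, must be at most `vocabulary size - 1`.
#' @return character vector of `k` words, most similar first.
#' @export
nearest_neighbors <- function(emb, word, k = 10L) {
  stopifnot(inherits(emb, "decade_embeddings"))
  if (!word %in% emb$vocabulary) stopf("word '%s' not in vocabulary", word)
  n <- length(emb$vocabulary)
  if (k >= n) stopf("k = %d but only %d other words exist", k, n - 1)
  v <- emb$vectors[word, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stopf("zero-norm vector for word '%s'", word)
  nrm <- sqrt(rowSums(emb$vectors^2))
  ok <- nrm > 0 & emb$vocabulary != word
  sims <- as.numeric(emb$vectors[ok, , drop = FALSE] %*% v) / (nrm[ok] * nv)
  cand <- emb$vocabulary[ok]
  ord <- order(-sims, cand, method = "radix")
  cand[ord][seq_len(k)]
}

#' Sample unrelated partner words
#'
#' Uniform seeded sample (without replacement) from the vocabulary minus the
#' word itself and its excluded neighbor set: the "inverse set" used for
#' non-neighbor baseline pairs.
#'
#' @param vocab full vocabulary.
#' @param word the target word.
#' @param excluded words to exclude (typically the selected neighbors).
#' @param k number of words to sample.
#' @param seed RNG seed.
#' @export
sample_non_neighbors <- function(vocab, word, excluded, k = 10L, seed = 1L) {
  complement <- setdiff(vocab, c(excluded, word))
  if (length(complement) < k)
    stopf("complement has %d words, need %d", length(complement), k)
  with_seed(seed, sample(complement, k))
}

#' Build the changed/unchanged stimulus pair set
#'
#' The full Study-2-style construction: classify the vocabulary by
#' cross-decade self-cosine, take the `n_changed` most-changed words
#' (ascending self-similarity) and the `n_unchanged` most stable words
#' (descending), then give every target `k_neighbors` nearest neighbors from
#' each of the two decades plus `k_non` randomly sampled non-neighbors
#' (excluding the selected neighbors).  Each target therefore contributes
#' `2 * k_neighbors + k_non` pairs before deduplication.
#'
#' @inheritParams classify_change
#' @param n_changed,n_unchanged how many targets of each class.
#' @param k_neighbors neighbors per decade per target (default 10).
#' @param k_non non-neighbor partners per target (default 10).
#' @param seed RNG seed for the non-neighbor sampling.
#' @return data.frame with `target`, `partner`, `pair_type`
#'   (`n1950` / `n1990` / `non_neighbor`), `change_status`, `self_sim`.
#' @export
build_stimulus_pairs <- function(series, t1 = 1950, t2 = 1990, threshold = 0.35,
                                 n_changed = 150L, n_unchanged = 150L,
                                 k_neighbors = 10L, k_non = 10L, seed = 1L) {
  cls <- classify_change(series, t1 = t1, t2 = t2, threshold = threshold)
  changed <- cls[cls$change_status == "changed", ]
  unchanged <- cls[cls$change_status == "unchanged", ]
  if (nrow(changed) < n_changed)
    stopf("only %d changed candidates below the threshold, need %d",
          nrow(changed), n_changed)
  if (nrow(unchanged) < n_unchanged)
    stopf("only %d unchanged candidates above the threshold, need %d",
          nrow(unchanged), n_unchanged)
  changed <- changed[order(changed$self_sim, changed$word), ][seq_len(n_changed), ]
  unchanged <- unchanged[order(-unchanged$self_sim, unchanged$word), ][seq_len(n_unchanged), ]
  targets <- rbind(changed, unchanged)
  e1 <- get_decade(series, t1)
  e2 <- get_decade(series, t2)
  vocab <- e1$vocabulary
  type1 <- paste0("n", t1)
  type2 <- paste0("n", t2)
  rows <- with_seed(seed, lapply(seq_len(nrow(targets)), function(i) {
    tw <- targets$word[i]
    nb1 <- nearest_neighbors(e1, tw, k_neighbors)
    nb2 <- nearest_neighbors(e2, tw, k_neighbors)
    nn <- sample_non_neighbors(vocab, tw, excluded = union(nb1, nb2), k = k_non,
                               seed = NULL)
    data.frame(target = tw,
               partner = c(nb1, nb2, nn),
               pair_type = c(rep(type1, k_neighbors), rep(type2, k_neighbors),
                             rep("non_neighbor", k_non)),
               change_status = targets$change_status[i],
               self_sim = targets$self_sim[i],
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign stimulus pairs to counterbalancing lists
#'
#' Builds `n_lists` lists of `targets_per_list` targets each (half changed,
#' half unchanged up to rounding, so 25-target lists hold 12 changed and 13
#' unchanged targets or vice versa), with each target contributing one pair
#' of each of the three types per list it appears in.  Construction proceeds
#' in rounds: each round partitions all targets across `2N / targets_per_list`
#' lists, every target appears once per round, and its per-type pair for that
#' round walks through a seeded permutation of its pairs -- so with as many
#' rounds as pairs per type, every pair of every target is covered by at
#' least one list.
#'
#' @param pairs pair table from [build_stimulus_pairs()].
#' @param n_lists number of counterbalancing lists (default 120).
#' @param targets_per_list targets per list (default 25, giving 75 pairs).
#' @param seed RNG seed.
#' @return data.frame with `list_id`, `target`, `partner`, `pair_type`,
#'   `change_status`.
#' @export
build_counterbalance_lists <- function(pairs, n_lists = 120L,
                                       targets_per_list = 25L, seed = 1L) {
  stopifnot(is.data.frame(pairs),
            all(c("target", "partner", "pair_type", "change_status") %in% names(pairs)))
  types <- unique(pairs$pair_type)
  if (length(types) != 3) stopf("expected exactly 3 pair types, got %d", length(types))
  tinfo <- unique(pairs[c("target", "change_status")])
  n_targets <- nrow(tinfo)
  per_type <- table(pairs$target, pairs$pair_type)
  if (any(per_type == 0))
    stopf("every target needs at least one pair of each type")
  k <- max(per_type)
  if ((n_targets %% targets_per_list) != 0)
    stopf("targets (%d) must divide evenly into lists of %d", n_targets, targets_per_list)
  lists_per_round <- n_targets %/% targets_per_list
  if ((n_lists %% lists_per_round) != 0)
    stopf("n_lists (%d) must be a multiple of %d (targets / targets_per_list)",
          n_lists, lists_per_round)
  rounds <- n_lists %/% lists_per_round
  if (rounds < k)
    stopf("coverage impossible: %d rounds of appearances but up to %d pairs per type per target (deficit %d)",
          rounds, k, k - rounds)

  changed_words <- tinfo$target[tinfo$change_status == "changed"]
  unchanged_words <- tinfo$target[tinfo$change_status != "changed"]
  # per-target seeded pair order per type, walked across the target's appearances
  pair_lookup <- split(pairs, pairs$target)

  with_seed(seed, {
    pair_order <- lapply(pair_lookup, function(df) {
      lapply(split(df$partner, df$pair_type), function(p)
        p[sample.int(length(p))][((seq_len(rounds) - 1) %% length(p)) + 1])
    })
    out <- vector("list", n_lists)
    list_id <- 0L
    for (r in seq_len(rounds)) {
      cw <- shuffle(changed_words)
      uw <- shuffle(unchanged_words)
      # changed quota per list this round: floor/ceil pattern, shuffled
      base_q <- length(cw) %/% lists_per_round
      extra <- length(cw) %% lists_per_round
      quota <- shuffle(c(rep(base_q + 1L, extra), rep(base_q, lists_per_round - extra)))
      ci <- 0L; ui <- 0L
      for (l in seq_len(lists_per_round)) {
        list_id <- list_id + 1L
        qc <- quota[l]
        qu <- targets_per_list - qc
        picks <- c(cw[ci + seq_len(qc)], uw[ui + seq_len(qu)])
        ci <- ci + qc; ui <- ui + qu
        rows <- lapply(picks, function(tw) {
          po <- pair_order[[tw]]
          data.frame(list_id = list_id, target = tw,
                     partner = vapply(po, `[[`, character(1), r),
                     pair_type = names(po),
                     change_status = pair_lookup[[tw]]$change_status[1],
                     stringsAsFactors = FALSE)
        })
        out[[list_id]] <- do.call(rbind, rows)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Filter rating records by data-quality criteria
#'
#' Keeps only records from participants who answered all catch trials
#' correctly (`catch_score >= min_catch`) and took strictly longer than
#' `min_minutes` minutes; a participant at exactly the duration bound is
#' excluded.  Per-filter exclusion counts are attached as the
#' `"exclusions"` attribute.
#'
#' @param records rating records with `participant_id`, `catch_score`,
#'   `duration` columns.
#' @param min_catch catch trials required correct (default 5 of 5).
#' @param min_minutes minimum task duration in minutes, exclusive bound
#'   (default 4).
#' @export
clean_ratings <- function(records, min_catch = 5L, min_minutes = 4) {
  stopifnot(is.data.frame(records),
            all(c("participant_id", "catch_score", "duration") %in% names(records)))
  by_p <- !duplicated(records$participant_id)
  fail_catch <- records$catch_score < min_catch
  fail_time <- records$duration <= min_minutes
  keep <- !(fail_catch | fail_time)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(
    participants_catch = length(unique(records$participant_id[by_p & fail_catch])),
    participants_duration = length(unique(records$participant_id[by_p & fail_time])),
    records_removed = sum(!keep))
  out
}

#' Collapse duplicated unordered word pairs
#'
#' When a target's two neighbor lists share a partner, the same unordered
#' pair exists under both neighbor types.  All rows for such a pair are
#' mapped to one canonical pair key whose `pair_type` is the type first
#' listed in the input; for rating records (rows carrying a
#' `participant_id`), repeated ratings of the same pair by the same
#' participant are then reduced to the first.
#'
#' @param records a pair table or rating record table with `target`,
#'   `partner` and `pair_type` columns.
#' @export
dedupe_pairs <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("target", "partner", "pair_type") %in% names(records)))
  key <- paste(pmin(records$target, records$partner),
               pmax(records$target, records$partner), sep = "\r")
  canon_type <- tapply(records$pair_type, key, `[[`, 1)
  out <- records
  out$pair_type <- as.vector(canon_type[key])
  if ("participant_id" %in% names(out)) {
    dup <- duplicated(paste(out$participant_id, key, sep = "\r"))
  } else {
    dup <- duplicated(key)
  }
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample ratings to a fixed count per pair and cohort
#'
#' Uniform seeded subsample so every retained pair has exactly `per_cohort`
#' ratings from each cohort, equalizing the weight of pairs that attracted
#' different numbers of raters.  Pairs with too few ratings in either cohort
#' are an error by default, or dropped (with the removed pairs recorded in
#' the `"dropped_pairs"` attribute) when `on_short = "drop"`.
#'
#' @param records rating records with `target`, `partner`, `cohort` columns.
#' @param per_cohort ratings to keep per (pair, cohort), default 5.
#' @param seed RNG seed.
#' @param on_short `"error"` or `"drop"`.
#' @export
subsample_ratings <- function(records, per_cohort = 5L, seed = 1L,
                              on_short = c("error", "drop")) {
  on_short <- match.arg(on_short)
  stopifnot(is.data.frame(records),
            all(c("target", "partner", "cohort") %in% names(records)))
  key <- paste(pmin(records$target, records$partner),
               pmax(records$target, records$partner), sep = "\r")
  grp <- paste(key, records$cohort, sep = "\r")
  counts <- table(grp)
  cohorts <- unique(records$cohort)
  short_grp <- names(counts)[counts < per_cohort]
  short_pairs <- unique(vapply(strsplit(short_grp, "\r"), function(x)
    paste(x[1], x[2], sep = "\r"), character(1)))
  # a pair present in only one cohort is short in the other
  pair_cohorts <- table(key, records$cohort)
  if (length(cohorts) > 1) {
    short_pairs <- union(short_pairs,
                         rownames(pair_cohorts)[apply(pair_cohorts < per_cohort, 1, any)])
  }
  if (length(short_pairs)) {
    if (on_short == "error") {
      show <- gsub("\r", "/", utils::head(short_pairs, 5))
      stopf("%d pair(s) have fewer than %d ratings in some cohort: %s",
            length(short_pairs), per_cohort, paste(show, collapse = ", "))
    }
    keep_pair <- !(key %in% short_pairs)
    records <- records[keep_pair, , drop = FALSE]
    key <- key[keep_pair]
    grp <- grp[keep_pair]
  }
  idx <- with_seed(seed, unlist(lapply(split(seq_along(grp), grp), function(i) {
    if (length(i) == per_cohort) i else i[sample.int(length(i), per_cohort)]
  }), use.names = FALSE))
  out <- records[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  if (length(short_pairs) && on_short == "drop")
    attr(out, "dropped_pairs") <- gsub("\r", "/", short_pairs)
  out
}
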