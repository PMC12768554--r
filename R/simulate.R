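#' Configuration for the drifting-embedding generator
#'
#' The generator plants two word classes on the unit sphere: "changed" words
#' whose meaning rotates toward a fresh random direction over the decades,
#' and "unchanged" words that move only by an undirected random-walk jitter.
#' Both motions are calibrated so the expected first-vs-last-decade
#' self-cosine hits `change_target_sim` (default 0.21) and
#' `stable_target_sim` (default 0.71) respectively, the anchor values for a
#' changed/unchanged stimulus set.
#'
#' @param n_words vocabulary size (default 300).
#' @param dim embedding dimension (default 50).
#' @param n_decades number of decades (default 10).
#' @param first_decade,decade_step year labels (defaults 1900 by 10).
#' @param n_changed number of changed words (default half the vocabulary).
#' @param change_target_sim,stable_target_sim expected first-vs-last cosine
#'   for the two classes.
#' @param base_drift_sd per-decade, per-coordinate random-walk scale (the
#'   cumulative drift).  `NULL` (default) means "calibrate from
#'   `stable_target_sim`"; a value overrides the calibration.
#' @param decade_noise_sd per-decade transient jitter scale, emulating the
#'   decade-idiosyncratic corpus-estimation noise that keeps even adjacent
#'   decades' RSMs imperfectly correlated.  `NULL` (default) means
#'   "calibrate from `adjacent_rsm_cor`".
#' @param adjacent_rsm_cor target mean Spearman correlation between adjacent
#'   decades' RSMs (default 0.70, the level observed for real decade
#'   embeddings); set `NULL` to disable the transient-noise component.
#' @param seed RNG seed.
#' @return a `drift_config` list.
#' @export
drift_config <- function(n_words = 300L, dim = 50L, n_decades = 10L,
                         first_decade = 1900L, decade_step = 10L,
                         n_changed = NULL, change_target_sim = 0.21,
                         stable_target_sim = 0.71, base_drift_sd = NULL,
                         decade_noise_sd = NULL, adjacent_rsm_cor = 0.70,
                         seed = 1L) {
  n_changed <- n_changed %||% (n_words %/% 2L)
  stopifnot(is_count(n_words), is_count(dim), is_count(n_decades), n_decades >= 1,
            is_count(n_changed), n_changed >= 0)
  if (n_changed > n_words) stopf("n_changed (%d) exceeds n_words (%d)", n_changed, n_words)
  for (s in c(change_target_sim, stable_target_sim)) {
    if (!is.numeric(s) || s <= -1 || s >= 1) stopf("target similarities must lie in (-1, 1)")
  }
  if (change_target_sim >= stable_target_sim)
    stopf("change_target_sim must be below stable_target_sim")
  structure(list(n_words = as.integer(n_words), dim = as.integer(dim),
                 n_decades = as.integer(n_decades),
                 first_decade = as.integer(first_decade),
                 decade_step = as.integer(decade_step),
                 n_changed = as.integer(n_changed),
                 change_target_sim = change_target_sim,
                 stable_target_sim = stable_target_sim,
                 base_drift_sd = base_drift_sd,
                 decade_noise_sd = decade_noise_sd,
                 adjacent_rsm_cor = adjacent_rsm_cor,
                 seed = as.integer(seed)),
            class = "drift_config")
}

# Core motion model shared by the generator and its calibration probes.
# u: unit base directions; a: unit anchor directions orthogonal to u;
# theta: per-word total rotation angle reached at the last decade.
# Per decade: progressive rotation toward the anchor (changed words), an
# accumulating random walk (sd_step) and a fresh transient jitter (sd_eps);
# rows re-normalized.
drift_paths <- function(u, a, theta, td, sd_step, sd_eps) {
  n <- nrow(u); d <- ncol(u)
  delta <- matrix(0, n, d)
  out <- vector("list", td)
  for (t in seq_len(td)) {
    frac <- if (td > 1L) (t - 1) / (td - 1) else 0
    th <- theta * frac
    clean <- cos(th) * u + sin(th) * a
    if (t > 1L && sd_step > 0)
      delta <- delta + matrix(stats::rnorm(n * d), n) * sd_step
    eps <- if (sd_eps > 0) matrix(stats::rnorm(n * d), n) * sd_eps else 0
    out[[t]] <- normalize_rows(clean + delta + eps)
  }
  out
}

# Monte-Carlo calibration of the generator's free motion parameters: the
# random-walk step sd (matching the unchanged-word first-vs-last cosine),
# the transient per-decade jitter sd (matching the target adjacent-decade
# RSM correlation) and the total rotation angle of changed words (matching
# the changed-word cosine net of all jitter).  The two sds are solved by
# alternating 1-D root finds (the couplings are mild, three sweeps
# suffice); every objective is evaluated on probe paths generated under a
# fixed seed so uniroot sees a deterministic function.  Results are cached
# per configuration.
calibrate_drift <- function(dim, n_decades, stable_target, change_target,
                            adjacent_rsm_cor = 0.70, base_drift_sd = NULL,
                            decade_noise_sd = NULL, n_probe = 400L,
                            probe_seed = 904001L) {
  key <- paste(dim, n_decades, stable_target, change_target,
               adjacent_rsm_cor %||% "off", base_drift_sd %||% "auto",
               decade_noise_sd %||% "auto", n_probe, sep = "|")
  if (!is.null(.chronolex_cache[[key]])) return(.chronolex_cache[[key]])
  steps <- n_decades - 1L
  probe_paths <- function(n, sd_step, sd_eps, theta = 0, seed_off = 0L) {
    with_seed(probe_seed + seed_off, {
      u <- normalize_rows(matrix(stats::rnorm(n * dim), n))
      a <- matrix(stats::rnorm(n * dim), n)
      a <- normalize_rows(a - u * rowSums(a * u))   # orthogonal to u
      drift_paths(u, a, rep(theta, n), n_decades, sd_step, sd_eps)
    })
  }
  selfcos <- function(p) mean(rowSums(p[[1]] * p[[length(p)]]))
  adjcor <- function(p) {
    rsms <- lapply(p, tcrossprod)   # unit rows, so these are cosine RSMs
    ut <- upper.tri(rsms[[1]])
    mean(vapply(seq_len(length(p) - 1L), function(t)
      stats::cor(rsms[[t]][ut], rsms[[t + 1L]][ut], method = "spearman"),
      numeric(1)))
  }
  solve_eps <- is.null(decade_noise_sd) && !is.null(adjacent_rsm_cor)
  solve_step <- is.null(base_drift_sd)
  if (solve_step && steps == 0L)
    stopf("cannot calibrate drift with a single decade; set base_drift_sd")
  sd_eps <- decade_noise_sd %||% 0
  sd_step <- base_drift_sd %||% 0.05
  if (solve_step || solve_eps) {
    for (sweep in seq_len(if (solve_step && solve_eps) 3L else 1L)) {
      if (solve_step) {
        f <- function(s) selfcos(probe_paths(n_probe, s, sd_eps)) - stable_target
        if (f(1e-6) < 0)
          stopf("infeasible: stable_target_sim %.2f exceeds the %.3f reachable under the transient jitter",
                stable_target, selfcos(probe_paths(n_probe, 1e-6, sd_eps)))
        sd_step <- stats::uniroot(f, lower = 1e-6, upper = 5, tol = 1e-4)$root
      }
      if (solve_eps) {
        g <- function(e) adjcor(probe_paths(100L, sd_step, e, seed_off = 2L)) -
          adjacent_rsm_cor
        sd_eps <- stats::uniroot(g, lower = 1e-6, upper = 5, tol = 1e-4)$root
      }
    }
  }
  mean_cos_changed <- function(theta)
    selfcos(probe_paths(n_probe, sd_step, sd_eps, theta = theta, seed_off = 1L))
  attainable <- mean_cos_changed(1e-6)
  if (change_target >= attainable - 1e-3)
    stopf("infeasible drift targets: changed-word cosine %.2f is not below the %.3f reachable under the jitter level",
          change_target, attainable)
  theta_max <- stats::uniroot(function(th) mean_cos_changed(th) - change_target,
                              lower = 1e-6, upper = pi - 1e-6, tol = 1e-4)$root
  out <- list(sd_step = sd_step, sd_eps = sd_eps, theta_max = theta_max)
  .chronolex_cache[[key]] <- out
  out
}

#' Simulate a drifting diachronic embedding series
#'
#' Decade-0 vectors are isotropic Gaussian directions on the unit sphere.
#' Word motion across decades has three components: a progressive spherical
#' rotation toward a fresh random anchor direction (changed words only), an
#' accumulating Gaussian random walk (the slow collective drift all words
#' share), and a fresh per-decade transient jitter that emulates
#' decade-idiosyncratic corpus-estimation noise -- the component that keeps
#' even adjacent decades' RSMs imperfectly correlated, as observed for real
#' decade embeddings.  Rows are re-normalized every decade.  Rotation angle
#' and both jitter scales are calibrated by Monte-Carlo root-finding (see the
#' package vignette) so the expected first-vs-last self-cosines of the two
#' word classes and the mean adjacent-decade RSM correlation match the
#' configured targets.  Because every decade is generated in one common
#' frame, the returned series is already aligned.
#'
#' Ground truth (changed word list, rotation angle, jitter scales) is
#' attached as the `"ground_truth"` attribute for recovery tests.
#'
#' @param cfg a [drift_config()].
#' @return an aligned [aligned_series()] of `n_decades`
#'   [decade_embeddings()].
#' @export
simulate_diachronic_embeddings <- function(cfg) {
  stopifnot(inherits(cfg, "drift_config"))
  n <- cfg$n_words; d <- cfg$dim; td <- cfg$n_decades
  years <- cfg$first_decade + cfg$decade_step * (seq_len(td) - 1L)
  needs_rotation <- cfg$n_changed > 0L
  cal <- if (td > 1L || needs_rotation) {
    calibrate_drift(d, td, cfg$stable_target_sim, cfg$change_target_sim,
                    adjacent_rsm_cor = cfg$adjacent_rsm_cor,
                    base_drift_sd = cfg$base_drift_sd,
                    decade_noise_sd = cfg$decade_noise_sd)
  } else {
    list(sd_step = cfg$base_drift_sd %||% 0,
         sd_eps = cfg$decade_noise_sd %||% 0, theta_max = 0)
  }
  words <- sprintf("w%0*d", nchar(n), seq_len(n))
  with_seed(cfg$seed, {
    u <- normalize_rows(matrix(stats::rnorm(n * d), n))
    changed_idx <- if (needs_rotation) sort(sample.int(n, cfg$n_changed)) else integer(0)
    a <- matrix(0, n, d)
    if (needs_rotation) {
      raw <- matrix(stats::rnorm(cfg$n_changed * d), cfg$n_changed)
      uc <- u[changed_idx, , drop = FALSE]
      a[changed_idx, ] <- normalize_rows(raw - uc * rowSums(raw * uc))
    }
    theta_word <- numeric(n)
    theta_word[changed_idx] <- cal$theta_max
    paths <- drift_paths(u, a, theta_word, td, cal$sd_step, cal$sd_eps)
    decs <- lapply(seq_len(td), function(t)
      decade_embeddings(years[t], words, paths[[t]]))
    structure(
      aligned_series(decs, aligned = TRUE, reference_decade = years[td]),
      ground_truth = list(changed = words[changed_idx],
                          theta_max = cal$theta_max, sd_step = cal$sd_step,
                          sd_eps = cal$sd_eps))
  })
}

#' Configuration for a simulated cohort learner
#'
#' @param label cohort name.
#' @param experienced_decades the decades the cohort lived through.
#' @param hypothesis the generating weighting scheme (`"early"`,
#'   `"uniform"`, `"recent"`).
#' @param base decay base (default 0.5).
#' @param rsm_noise_sd cellwise Gaussian noise on the cohort RSM.
#' @param seed RNG seed.
#' @export
cohort_sim_config <- function(label, experienced_decades,
                              hypothesis = c("early", "uniform", "recent"),
                              base = 0.5, rsm_noise_sd = 0, seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  exposure <- cohort_exposure(label, experienced_decades)
  structure(list(label = exposure$label,
                 experienced_decades = exposure$experienced_decades,
                 hypothesis = hypothesis, base = base,
                 rsm_noise_sd = rsm_noise_sd, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a cohort's semantic RSM under a known weighting hypothesis
#'
#' The cohort's space is the weighted mean of the decade RSMs it experienced,
#' weighted under the configured hypothesis, plus symmetric cellwise Gaussian
#' noise (diagonal reset to 1).  The generating hypothesis is attached as the
#' `"hypothesis"` attribute, the ground truth for recovery checks.
#'
#' @param series an [aligned_series()] covering the experienced decades.
#' @param cfg a [cohort_sim_config()].
#' @return an [new_rsm()].
#' @export
simulate_cohort_rsm <- function(series, cfg) {
  stopifnot(inherits(series, "aligned_series"), inherits(cfg, "cohort_sim_config"))
  keys <- as.character(cfg$experienced_decades)
  missing <- setdiff(keys, names(series$decades))
  if (length(missing))
    stopf("experienced decades not in the series: %s", paste(missing, collapse = ", "))
  rsms <- lapply(series$decades[keys], cosine_rsm)
  w <- compute_weights(cfg$hypothesis, cfg$experienced_decades, base = cfg$base)
  m <- weighted_mean_rsm(rsms, w)
  noised <- with_seed(cfg$seed, add_symmetric_noise(m, cfg$rsm_noise_sd))
  out <- new_rsm(noised, rownames(m),
                 source = sprintf("cohort %s (simulated)", cfg$label),
                 validate = FALSE)
  attr(out, "hypothesis") <- cfg$hypothesis
  out
}

#' Configuration for the association-response sampler
#'
#' @param responses_per_cue target responses per cue (default 15); each
#'   synthetic participant contributes 3 distinct responses per cue, so
#'   `ceiling(responses_per_cue / 3)` participants are generated.
#' @param temperature softmax concentration; as it approaches 0, responses
#'   concentrate deterministically on the most similar words.  The default
#'   0.3 keeps responses similarity-driven while spreading them over many
#'   distinct words per cue, as real association norms do.
#' @param age_range half-open `[min, max)` participant age window.
#' @param seed RNG seed.
#' @export
response_sim_config <- function(responses_per_cue = 15L, temperature = 0.3,
                                age_range = c(20, 35), seed = 1L) {
  stopifnot(is_count(responses_per_cue), responses_per_cue >= 1,
            is.numeric(temperature), temperature > 0,
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(responses_per_cue = as.integer(responses_per_cue),
                 temperature = temperature, age_range = age_range,
                 seed = as.integer(seed)),
            class = "response_sim_config")
}

#' Simulate word-association responses from an agent's RSM
#'
#' For every cue, each synthetic participant produces 3 distinct responses
#' sampled without replacement from the non-cue vocabulary with probability
#' proportional to `exp(similarity / temperature)` under the agent's RSM.
#' Participant ages are uniform over the configured cohort window, so cohort
#' membership (which is what the analyses use) is exact by construction.
#'
#' @param agent_rsm the agent's internal similarity space ([new_rsm()]).
#' @param cues cue words (subset of the RSM vocabulary); default all words.
#' @param cfg a [response_sim_config()].
#' @return a long-format association record data.frame (`participant_id`,
#'   `age`, `cue`, `response`, `position`).
#' @export
simulate_association_responses <- function(agent_rsm, cues = NULL, cfg) {
  stopifnot(inherits(cfg, "response_sim_config"))
  vocab <- rownames(agent_rsm)
  cues <- cues %||% vocab
  missing <- setdiff(cues, vocab)
  if (length(missing)) stopf("cues not in the RSM vocabulary: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  m <- unclass(as.matrix(agent_rsm))
  n_part <- ceiling(cfg$responses_per_cue / 3)
  with_seed(cfg$seed, {
    ages <- sample(seq(cfg$age_range[1], cfg$age_range[2] - 1), n_part, replace = TRUE)
    ids <- sprintf("P%0*d", nchar(n_part), seq_len(n_part))
    out <- vector("list", n_part * length(cues))
    k <- 0L
    for (ci in seq_along(cues)) {
      cue <- cues[ci]
      others <- vocab[vocab != cue]
      logits <- m[cue, others] / cfg$temperature
      for (p in seq_len(n_part)) {
        resp <- sample_softmax(others, logits, 3L)
        k <- k + 1L
        out[[k]] <- data.frame(participant_id = ids[p], age = ages[p], cue = cue,
                               response = resp, position = 1:3,
                               stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Configuration for the ordinal-rating generator
#'
#' Ratings arise from a latent relatedness value -- an affine map of the
#' agent's RSM similarity plus logistic noise -- cut at 6 ordered thresholds
#' into the 0-6 scale.  Logistic (rather than Gaussian) noise makes the
#' generator exactly a proportional-odds model, so an ordinal ML fit on the
#' generated data should recover `latent_scale / latent_noise_sd` as the
#' similarity slope.
#'
#' @param thresholds 6 strictly increasing cutpoints.
#' @param latent_intercept,latent_scale affine map from similarity to the
#'   latent scale.
#' @param latent_noise_sd scale of the logistic noise (0 = deterministic).
#' @param raters_per_pair_per_cohort default 5.
#' @param seed RNG seed.
#' @export
rating_sim_config <- function(thresholds = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
                              latent_intercept = 0, latent_scale = 6,
                              latent_noise_sd = 1,
                              raters_per_pair_per_cohort = 5L, seed = 1L) {
  stopifnot(length(thresholds) >= 1, !is.unsorted(thresholds, strictly = TRUE),
            is.numeric(latent_noise_sd), latent_noise_sd >= 0,
            is_count(raters_per_pair_per_cohort))
  structure(list(thresholds = thresholds, latent_intercept = latent_intercept,
                 latent_scale = latent_scale, latent_noise_sd = latent_noise_sd,
                 raters_per_pair_per_cohort = as.integer(raters_per_pair_per_cohort),
                 seed = as.integer(seed)),
            class = "rating_sim_config")
}

#' Simulate relatedness ratings for a stimulus pair set
#'
#' Each synthetic rater rates every pair: the latent relatedness is
#' `latent_intercept + latent_scale * similarity + logistic noise`, and the
#' rating is the number of thresholds the latent value exceeds.  Generated
#' keepers carry a perfect catch score and a plausible duration; optional
#' planted violators (failing the catch-trial or duration filter) exercise
#' the data-hygiene filters.
#'
#' @param agent_rsm the cohort's similarity space.
#' @param pairs pair table with `target`, `partner` (and optionally
#'   `pair_type`, `change_status`) columns.
#' @param cfg a [rating_sim_config()].
#' @param cohort `"YA"` or `"OA"` (sets the age window: 18-33 or 63-92), or a
#'   list `list(label =, age_range =)`.
#' @param n_violators synthetic participants violating the quality filters.
#' @return rating records: `participant_id`, `age`, `cohort`, `target`,
#'   `partner`, `pair_type`, `change_status`, `rating` (0-6 by default),
#'   `unknown_flag`, `catch_score`, `duration`.
#' @export
simulate_ratings <- function(agent_rsm, pairs, cfg, cohort = "YA",
                             n_violators = 0L) {
  stopifnot(inherits(cfg, "rating_sim_config"), is.data.frame(pairs),
            all(c("target", "partner") %in% names(pairs)))
  if (is.character(cohort)) {
    cohort <- switch(match.arg(cohort, c("YA", "OA")),
                     YA = list(label = "YA", age_range = c(18, 34)),
                     OA = list(label = "OA", age_range = c(63, 93)))
  }
  vocab <- rownames(agent_rsm)
  missing <- setdiff(unique(c(pairs$target, pairs$partner)), vocab)
  if (length(missing)) stopf("pair words not in the RSM vocabulary: %s",
                             paste(utils::head(missing, 5), collapse = ", "))
  m <- unclass(as.matrix(agent_rsm))
  sim <- m[cbind(pairs$target, pairs$partner)]
  np <- nrow(pairs)
  n_raters <- cfg$raters_per_pair_per_cohort
  with_seed(cfg$seed, {
    total <- n_raters + n_violators
    ids <- sprintf("%s%0*d", cohort$label, nchar(total), seq_len(total))
    ages <- sample(seq(cohort$age_range[1], cohort$age_range[2] - 1), total,
                   replace = TRUE)
    mk <- function(r, catch, dur) {
      noise <- if (cfg$latent_noise_sd > 0)
        stats::rlogis(np, 0, cfg$latent_noise_sd) else 0
      latent <- cfg$latent_intercept + cfg$latent_scale * sim + noise
      rating <- rowSums(outer(latent, cfg$thresholds, `>`))
      data.frame(participant_id = ids[r], age = ages[r], cohort = cohort$label,
                 target = pairs$target, partner = pairs$partner,
                 pair_type = pairs$pair_type %||% NA_character_,
                 change_status = pairs$change_status %||% NA_character_,
                 rating = as.integer(rating), unknown_flag = FALSE,
                 catch_score = catch, duration = dur,
                 stringsAsFactors = FALSE)
    }
    keepers <- lapply(seq_len(n_raters), function(r)
      mk(r, catch = 5L, dur = stats::runif(1, 5, 20)))
    violators <- lapply(seq_len(n_violators), function(v) {
      r <- n_raters + v
      if (v %% 2L == 1L) mk(r, catch = sample(0:4, 1), dur = stats::runif(1, 5, 20))
      else mk(r, catch = 5L, dur = stats::runif(1, 1, 4))
    })
    res <- do.call(rbind, c(keepers, violators))
    rownames(res) <- NULL
    res
  })
}
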