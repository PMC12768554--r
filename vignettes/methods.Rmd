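---
title: "Methods: relating diachronic semantic spaces to age-cohort semantic spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relating diachronic semantic spaces to age-cohort semantic spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronolex)
```

## The problem

Word meanings change at the level of a language: the nearest neighbors of
*icon* in a 1950s corpus and in a 1990s corpus are different words.  People,
however, learn a language across their lifespan, so members of different age
cohorts have experienced different historical mixtures of those meanings.
`chronolex` implements the analysis chain needed to ask how the two are
related: are an age cohort's word similarities best explained by weighting
the meanings of early decades most (an early-weighted mean, H1), all
experienced decades equally (an unweighted mean, H2), or recent decades most
(a recent-weighted mean, H3)?

Every data source is reduced to a common currency, the **representational
similarity matrix (RSM)**: a symmetric word-by-word similarity matrix over a
fixed, lexicographically ordered vocabulary.  RSMs abstract away the format
of the underlying data (vectors, cue-response counts, Likert ratings), and
two RSMs are compared by **representational similarity analysis (RSA)**: the
Spearman rank correlation of their off-diagonal upper triangles, extracted
row-major.  Rank correlation makes every comparison invariant to monotone
distortions of either similarity scale.

## Data sources and their RSMs

**Diachronic embeddings.**  Per-decade word vectors (word2vec text format)
are consumed, never trained.  Decades are restricted to their common
vocabulary (`intersect_vocabulary()`, sorted lexicographically so that
upper-triangle extraction is reproducible) and mapped into one frame with
orthogonal Procrustes rotations (`align_series()`).  Each decade is rotated
*directly* onto a single reference decade (default: the latest) rather than
chained decade-to-decade; direct mapping keeps every pair of decades
comparable and avoids accumulating alignment error along the chain.  The
rotation is the SVD closed form `R = UV'` of `X'Y`, the minimizer of the
Frobenius distance over orthogonal maps.  Decade RSMs are cosine
similarities of the aligned rows (`cosine_rsm()`); stored vectors are never
re-normalized in place, and zero-norm vectors are excluded with a warning
rather than imputed, since their cosine is undefined.

**Association networks.**  Cue-response records (one row per response, up to
3 responses per cue per participant) are aggregated per age cohort into a
directed count network (`build_network()`).  Cohort windows are half-open
`[min, max)` intervals so a 20-35 / 35-50 / 50-90 split partitions the age
axis.  Cues with fewer than 15 responses are dropped (inclusive threshold:
exactly 15 survives), then the count matrix passes through the
similarity chain of `assoc_similarity()`: PPMI weighting, row normalization
to a transition matrix, a decaying Katz random walk
`sum_k alpha^k P^k = (I - alpha P)^{-1}` that adds exponentially discounted
indirect paths, a second PPMI transform, row normalization to conditional
probabilities, and cosine similarity between rows.  Both PPMI stages share
one base-2 implementation.  The decay parameter `alpha` has no
published value for this procedure; it defaults to 0.75 and is exposed as an
explicit knob, because reconstruction quality depends on it.  Response
position (R1-R3) is not weighted -- no weighting scheme is documented for
the procedure being mirrored.

**Relatedness ratings.**  Ordinal 0-6 judgments of word pairs.  Quality
filters keep participants with all 5 catch trials correct and a duration
strictly longer than 4 minutes (`clean_ratings()`); duplicated unordered
pairs (a partner shared between a target's two neighbor lists) collapse onto
the first-listed pair type (`dedupe_pairs()`); and ratings are subsampled to
exactly 5 per pair per cohort (`subsample_ratings()`) so heavily rated pairs
do not dominate.

## Hypothesis RSMs

`compute_weights()` builds the three lifespan weighting schemes over a
decade axis with unnormalized weights `base^x`, `base = 0.5`, where `x`
counts decades from the favored end; weights are then normalized.  The
exponent's offset convention (whether the favored decade carries `base^0` or
`base^1`) is irrelevant after normalization, so the favored-end-at-zero
convention was chosen.  `weighted_mean_rsm()` takes the cellwise convex
combination, and `hypothesis_rsa()` correlates a behavioral RSM with all
three combinations, reporting every argmax on a tie rather than breaking it
silently.  Following the printed analyses, the Study-1-style comparison uses
the full decade axis for every cohort by default; restricting to a cohort's
experienced decades (`cohort_exposure()`) is available and is what the
simulation-recovery analyses use, since there the generating truth is
defined over the experienced window.

`simulate_hypothesis_pattern()` produces the schematic cohort-by-decade
correlation matrix for a hypothesis.  Its demonstrations use small cell
noise (0.01): the pattern it illustrates is structural, and the structural
gaps between adjacent decades' correlations are only a few hundredths, so
large noise obscures a signature that the analysis itself (which averages
over decades) still recovers comfortably at noise 0.05.

## Statistical machinery

**Permutation test for the temporal gradient.**  The observed statistic is
the Spearman correlation between temporal distance `|t_i - t_j|` and
representational *dissimilarity* (minus the pairwise RSA), positive when
similarity decays with distance -- the sign convention in which such
gradients are conventionally reported.  The null shuffles decade labels and
recomputes; the central 95% interval uses the empirical 2.5/97.5 percentiles.
Constant pairwise-RSA vectors (which label shuffles can create) yield a
flagged degenerate result instead of an error.

**Reliability.**  `split_half_reliability()` splits *participants*, not
records, into random halves -- record-level splits would leak
within-participant structure across halves -- and averages the half-vs-half
RSA over splits (5 splits is typical for association data, 100 for
ratings; both remain parameters since no single count is canonical).
`interannotator_agreement()` correlates each rater with the item means of
all other raters and averages.

**Linear decade ablation.**  `fit_linear()` is OLS with intercept (through
`stats::lm`), predicting a behavioral RSM's upper-triangle cells from the
matching cells of the ten decade RSMs.  `ablate_linear()` removes one decade
at a time and, per cross-validation fold (5 by default), reports
full-minus-ablated differences: AIC on the training fit (AIC counts the
intercept and the residual scale among its parameters), log-likelihood and
R-squared on the held-out fold using the training ML sigma.  A nested
extra-sum-of-squares F-test on the complete data accompanies each decade;
the ten tests are reported with raw p-values, uncorrected, matching how such
ablation batteries are conventionally reported.

**Ordinal models.**  `fit_ordinal()` is a maximum-likelihood
cumulative-logit (proportional-odds) model: `MASS::polr` for three or more
observed levels, and an internal BFGS fit of the one-cutpoint model for the
two-level boundary case polr does not cover (that case is mathematically a
logistic regression, which is what makes an independent `glm` oracle test
possible).  A Bayesian multilevel treatment with random subject and pair
effects is out of scope here; the fixed-effects ML fit with k-fold
cross-validated predictive density is the package's deliberate, documented
replacement, and all tests of this module are property-based (parameter
recovery, calibration) rather than comparisons to posterior summaries.
`ablate_ordinal()` scores each ablation by the summed held-out log
predictive density difference (ELPD; ablated minus full, so useful
predictors go negative), with a fold-wise standard error by default and a
pointwise one alongside, and flags `|ELPD difference| < 4` as negligible --
the conventional rule of thumb.  Folds are stratified by response level so
every training fold sees all categories.  `fit_factorial_ordinal()` fits the
age x pair-type x meaning-change rating model with effect coding for age
(reference YA) and change (reference unchanged) and dummy coding for pair
type (reference non-neighbor), and returns latent-scale marginal means and
pairwise contrasts with Wald intervals via `emmeans`.

Convergence of the ordinal fits uses a gradient tolerance of `reltol =
1e-12` with at most 500 BFGS iterations and deterministic initialization
(polr's empirical-logit cutpoints, zero slopes); the `converged` flag
reports the optimizer's own status honestly, and non-convergence returns a
flagged partial result rather than an error.

## Stimulus construction

`classify_change()` labels words by their aligned 1950-vs-1990 self-cosine:
below 0.35 changed, above 0.35 unchanged, *exactly* at the threshold
unassigned and excluded (the classification uses strict inequalities, so the
boundary is undefined by construction).  `build_stimulus_pairs()` takes the
150 lowest self-similarity words as changed targets and the 150 highest as
unchanged, then pairs each target with its 10 nearest neighbors in each of
the two decades (cosine, ties broken lexicographically for determinism) and
10 uniform samples from the complement of its selected neighbors.
`build_counterbalance_lists()` assembles 120 lists of 25 targets (12 or 13
changed, the rest unchanged) x 3 pairs each = 75 pairs, by rounds: each
round partitions all 300 targets over 12 lists, and a target's pair for each
type walks a seeded permutation of its 10 pairs across its 10 appearances,
which guarantees every pair is covered by at least one list.

## The synthetic-data generator

The generator exists so the full chain runs, and is testable, with no
external corpora.  What it emulates -- and what it does not -- determines
what passing tests mean.

**Drifting embeddings** (`simulate_diachronic_embeddings()`).  Words start
as isotropic random directions on the unit sphere (dimension 50 by default,
10 decades, 300 words).  Motion has three components:

* a progressive rotation toward a fresh random orthogonal anchor, applied
  only to the planted *changed* words;
* a slow accumulating random walk shared by all words (the collective
  drift that makes distant decades less similar than near ones);
* a fresh per-decade transient jitter, emulating decade-idiosyncratic
  corpus-estimation noise.  This component is what keeps even adjacent
  decades' RSMs imperfectly correlated; without it a random-walk-only
  generator produces adjacent-decade RSM correlations near 0.93 and a
  concave decay profile, unlike real decade embeddings, whose profile is
  convex (a large lag-1 drop around 0.7, then slow decay).

The three motion scales are calibrated by one-dimensional root finding
(`uniroot`) on Monte-Carlo estimates computed under a fixed internal probe
seed, so calibration is deterministic and cached per configuration: the walk
scale targets a mean unchanged-word first-vs-last self-cosine of 0.71, the
transient scale targets a mean adjacent-decade RSM Spearman correlation of
0.70, and the changed-word rotation angle targets a mean changed-word
self-cosine of 0.21 net of all jitter.  The two cosine anchors are the
means around which a changed/unchanged stimulus set is built; infeasible
target combinations (e.g. a changed-word target not below what the jitter
alone allows) raise an error.  Realized means land within about 0.01 of the
targets; the realized spread (about 0.1 for changed words) means a small
tail of changed words crosses the 0.35 threshold, as in real stimulus sets.

**Cohort learners** (`simulate_cohort_rsm()`).  A cohort's semantic space is
the weighted mean of its experienced decades' RSMs under a known hypothesis
plus symmetric cellwise Gaussian noise -- exactly the structure the recovery
analysis assumes, which is what makes recovery a well-posed check of the
inference machinery rather than of the generator.

**Association responses** (`simulate_association_responses()`).  Each
synthetic participant produces 3 distinct responses per cue, sampled without
replacement with probability proportional to `exp(similarity /
temperature)` under the agent's RSM.  The softmax is a stand-in -- no
generative model of association responses is given by the work this
emulates -- and its temperature has no published value.  The default 0.3
keeps responses similarity-driven while spreading them across many distinct
words per cue, as real association norms do; a near-zero temperature would
make all participants produce identical response triples, and then
additional participants add no information.  Participant ages are uniform
in the cohort window, since cohort membership rather than age itself drives
every analysis.

**Ordinal ratings** (`simulate_ratings()`).  A pair's latent relatedness is
an affine map of the agent's RSM similarity plus *logistic* noise, cut at 6
ordered thresholds into the 0-6 scale.  Logistic rather than Gaussian noise
makes the generator exactly a proportional-odds model, so the ordinal ML
fit should recover `latent_scale / latent_noise_sd` as the similarity
slope -- closing the loop between the generator and the model family.
Generated keepers carry perfect catch scores and plausible durations;
planted violators exercise the hygiene filters.

**What the generator does not emulate:** Zipfian word frequencies,
morphology, polysemy, age-of-acquisition structure, response chaining in
associations, rater idiosyncrasies beyond exchangeable noise, and any
retrieval or cognitive-aging process.  Tests passing on this generator
therefore certify the pipeline's statistical machinery (alignment, similarity
chains, RSA, recovery, calibration, ablation inference), not claims about
real corpora or real participants.

## Numerical choices and degenerate inputs

* Spearman correlations use average ranks for ties throughout.
* RSMs must be symmetric within 1e-10 (1e-8 at extraction); cosine RSMs are
  clamped into `[-1, 1]` and carry an exact unit diagonal.
* `katz_walk()` requires `alpha` in (0, 1) and raises a "use a smaller
  alpha" error if `I - alpha P` is singular.
* Degenerate constant upper triangles yield flagged results (`degenerate =
  TRUE`, `rho = NA`) in RSA and the permutation test, not errors.
* Exact nearest-neighbor similarity ties break lexicographically; argmax
  ties in `hypothesis_rsa()` are reported, never broken.
* All randomized routines take explicit seeds, restore the caller's RNG
  state, and are bitwise reproducible.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run the chain at 100-word, 10-decade
spaces for hypothesis recovery (50 seeded runs per hypothesis at cohort-RSM
noise 0.05), 300-360 word spaces for stimulus construction and calibration
checks, 1,000 null replications for the F-test calibration, and 20,000
observations for ordinal slope recovery -- sizes at which every Monte-Carlo
rate involved is stable to a few percent, chosen as the package's own
standard demonstration conditions.
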