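#' Age-cohort specification
#'
#' Cohort windows are half-open intervals `[min_age, max_age)`, so adjacent
#' cohorts such as 20-35 / 35-50 / 50-90 partition the age axis with boundary
#' ages going to the older bin's lower edge.
#'
#' @param label cohort name, e.g. `"20-35"`.
#' @param min_age,max_age years; inclusive lower bound, exclusive upper bound.
#' @export
cohort_spec <- function(label, min_age, max_age) {
  stopifnot(is.numeric(min_age), is.numeric(max_age))
  if (!(min_age < max_age)) stopf("min_age must be < max_age")
  structure(list(label = as.character(label), min_age = min_age, max_age = max_age),
            class = "cohort_spec")
}

#' Read word-association records from CSV
#'
#' Two layouts are supported.  `"wide"` mirrors the Small World of Words
#' export: columns `participant_id, age, cue, R1, R2, R3`, with missing
#' responses as empty cells; it is reshaped to one row per response.
#' `"long"` expects `participant_id, age, cue, response, position`.
#'
#' @param path CSV file path.
#' @param format `"wide"` or `"long"`.
#' @return data.frame with columns `participant_id`, `age`, `cue`,
#'   `response`, `position` (position in 1..3).
#' @export
read_association_csv <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("participant_id", "age", "cue", "response", "position")
    missing <- setdiff(need, names(df))
    if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))
    out <- df[need]
  } else {
    need <- c("participant_id", "age", "cue", "R1", "R2", "R3")
    missing <- setdiff(need, names(df))
    if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))
    pieces <- lapply(1:3, function(k) {
      resp <- as.character(df[[paste0("R", k)]])
      keep <- !is.na(resp) & nzchar(trimws(resp))
      data.frame(participant_id = df$participant_id[keep], age = df$age[keep],
                 cue = df$cue[keep], response = trimws(resp[keep]),
                 position = k, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, pieces)
    out <- out[order(match(out$participant_id, df$participant_id)), ]
    rownames(out) <- NULL
  }
  validate_association_records(out)
  out
}

validate_association_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("participant_id", "age", "cue", "response", "position")
  missing <- setdiff(need, names(records))
  if (length(missing)) stopf("missing columns: %s", paste(missing, collapse = ", "))
  if (nrow(records)) {
    if (!all(records$position %in% 1:3))
      stopf("response position must be in {1, 2, 3}")
    if (any(records$age < 0)) stopf("negative ages in association records")
  }
  invisible(records)
}

#' Aggregate association records into a cohort's directed network
#'
#' An edge i -> j is created whenever any in-cohort participant produced
#' response j to cue i; edge weight is the count of such events.  All three
#' response positions are weighted equally.  The vocabulary is the
#' lexicographically sorted union of cues and responses; words appearing only
#' as responses keep zero out-rows and contribute as features (columns) only.
#'
#' @param records association records (see [read_association_csv()]).
#' @param cohort optional [cohort_spec()]; when given, only records with
#'   `min_age <= age < max_age` are counted.
#' @return an `assoc_network`: list with `vocabulary`, dense integer `counts`
#'   (cue rows x response columns over the full vocabulary) and
#'   `responses_per_cue` (row sums).
#' @export
build_network <- function(records, cohort = NULL) {
  validate_association_records(records)
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_spec"))
    keep <- records$age >= cohort$min_age & records$age < cohort$max_age
    records <- records[keep, , drop = FALSE]
  }
  vocab <- stringSort(unique(c(records$cue, records$response)))
  n <- length(vocab)
  counts <- matrix(0L, n, n, dimnames = list(vocab, vocab))
  if (nrow(records)) {
    tab <- table(factor(records$cue, levels = vocab),
                 factor(records$response, levels = vocab))
    counts[] <- as.integer(tab)
  }
  structure(
    list(vocabulary = vocab, counts = counts,
         responses_per_cue = rowSums(counts),
         cohort = if (is.null(cohort)) NULL else cohort$label),
    class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network: %d words, %d responses%s\n",
              length(x$vocabulary), sum(x$counts),
              if (is.null(x$cohort)) "" else sprintf(", cohort %s", x$cohort)))
  invisible(x)
}

#' Drop cues with too few responses
#'
#' Mirrors the at-least-15-responses-per-cohort cue filter: cues whose row sum
#' falls below `min_responses` are removed (the threshold is inclusive, so a
#' cue with exactly `min_responses` responses is retained).  Words that are
#' not cues (zero out-row) are untouched as long as they still occur in a
#' retained cue's responses.  Filtering is applied once, not iterated.
#'
#' @param net an `assoc_network`.
#' @param min_responses minimum responses per cue (default 15).
#' @export
filter_cues <- function(net, min_responses = 15L) {
  stopifnot(inherits(net, "assoc_network"))
  if (!is_count(min_responses) || min_responses < 1) stopf("min_responses must be >= 1")
  rpc <- net$responses_per_cue
  is_cue <- rpc > 0
  keep_cues <- names(rpc)[is_cue & rpc >= min_responses]
  if (!length(keep_cues)) stopf("all cues removed by the min_responses = %d filter", min_responses)
  sub <- net$counts[keep_cues, , drop = FALSE]
  responses <- colnames(sub)[colSums(sub) > 0]
  vocab <- stringSort(union(keep_cues, responses))
  n <- length(vocab)
  counts <- matrix(0L, n, n, dimnames = list(vocab, vocab))
  counts[keep_cues, responses] <- sub[, responses, drop = FALSE]
  structure(
    list(vocabulary = vocab, counts = counts,
         responses_per_cue = rowSums(counts), cohort = net$cohort),
    class = "assoc_network")
}

#' Positive pointwise mutual information
#'
#' `out[i, j] = max(0, log2(p(i, j) / (p(i) p(j))))` with the joint and
#' marginal probabilities taken from the matrix's own totals.  Zero cells stay
#' zero.  Used twice in the similarity chain (before and after the random
#' walk), with the same base-2 implementation at both stages.
#'
#' @param m non-negative numeric matrix with a positive grand total.
#' @export
ppmi_transform <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stopf("PPMI input must be non-negative")
  total <- sum(m)
  if (total <= 0) stopf("PPMI input must have a positive grand total")
  p <- m / total
  pr <- rowSums(p)
  pc <- colSums(p)
  expected <- outer(pr, pc)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  nz <- p > 0 & expected > 0
  out[nz] <- pmax(0, log2(p[nz] / expected[nz]))
  out
}

#' Row-normalize a non-negative matrix to transition probabilities
#'
#' Each nonzero row is scaled to sum to 1; all-zero rows stay zero and are
#' reported with a warning (they correspond to words that never act as cues).
#'
#' @param m non-negative numeric matrix.
#' @export
row_normalize <- function(m) {
  m <- as.matrix(m)
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero))
    warnf("%d all-zero row(s) left unnormalized", sum(zero))
  out <- m
  out[!zero, ] <- m[!zero, , drop = FALSE] / rs[!zero]
  out
}

#' Decaying (Katz) random walk over a transition matrix
#'
#' Computes the geometric walk sum `sum_{k >= 0} alpha^k P^k` in closed form
#' as `(I - alpha P)^{-1}`, adding exponentially discounted indirect paths to
#' the direct associations.  Requires `alpha` in (0, 1) and
#' `alpha * spectralradius(P) < 1` for the series to converge.
#'
#' @param P square transition matrix (typically row-stochastic).
#' @param alpha decay parameter in (0, 1); default 0.75.
#' @export
katz_walk <- function(P, alpha = 0.75) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stopf("P must be square")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stopf("alpha must lie strictly in (0, 1)")
  M <- diag(nrow(P)) - alpha * P
  out <- tryCatch(solve(M),
                  error = function(e)
                    stopf("(I - alpha P) is singular; use a smaller alpha (%s)",
                          conditionMessage(e)))
  dimnames(out) <- dimnames(P)
  out
}

#' Association-network similarity RSM
#'
#' The full similarity chain over an association network: PPMI weighting of
#' the raw counts, row normalization to a transition matrix, decaying Katz
#' random walk, a second PPMI transform of the walk matrix, row normalization
#' to conditional probabilities, and finally cosine similarity between the
#' rows.  Words whose final-stage row is all zero (typically words that never
#' occur as cues) have no defined similarity and are dropped with a warning.
#'
#' @param net an `assoc_network` (usually after [filter_cues()]).
#' @param alpha Katz decay parameter, see [katz_walk()].
#' @return an [new_rsm()] tagged `"cohort association"`.
#' @export
assoc_similarity <- function(net, alpha = 0.75) {
  stopifnot(inherits(net, "assoc_network"))
  if (!length(net$vocabulary) || sum(net$counts) == 0)
    stopf("empty association network")
  a1 <- ppmi_transform(net$counts)
  p1 <- suppressWarnings(row_normalize(a1))
  w <- katz_walk(p1, alpha = alpha)
  a2 <- ppmi_transform(w)
  p2 <- suppressWarnings(row_normalize(a2))
  nrm <- sqrt(rowSums(p2^2))
  keep <- nrm > 0
  if (!any(keep)) stopf("no rows with nonzero similarity support")
  if (any(!keep))
    warnf("dropping %d word(s) with zero final-stage rows from the similarity RSM",
          sum(!keep))
  vn <- p2[keep, , drop = FALSE] / nrm[keep]
  s <- tcrossprod(vn)
  s <- (s + t(s)) / 2
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  tag <- if (is.null(net$cohort)) "cohort association"
         else sprintf("cohort association %s", net$cohort)
  new_rsm(s, net$vocabulary[keep], source = tag, validate = FALSE)
}
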