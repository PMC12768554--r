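#' Representational similarity matrices
#'
#' An `rsm` is a symmetric word-by-word similarity matrix over an ordered
#' vocabulary, the common currency that every data source in the package is
#' reduced to before comparison.  It is stored as a plain numeric matrix with
#' the vocabulary in its dimnames, a `source` attribute recording where the
#' similarities came from (e.g. `"corpus decade 1950"`, `"cohort association"`,
#' a hypothesis label), and class `rsm`.
#'
#' Cosine-based sources must be symmetric to within 1e-10, carry a unit
#' diagonal and have all values in `[-1, 1]`; behaviour-derived or noised
#' sources are only required to be symmetric.
#'
#' @param mat square numeric matrix of similarities.
#' @param vocabulary character vector of words, one per row/column.  Defaults
#'   to the rownames of `mat`.
#' @param source short tag describing the data source.
#' @param validate check symmetry (and, for cosine-like sources, range and
#'   diagonal) before returning.
#' @return an object of class `rsm`.
#' @export
new_rsm <- function(mat, vocabulary = rownames(mat), source = "unknown",
                    validate = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stopf("an RSM must be square, got %dx%d", nrow(mat), ncol(mat))
  if (is.null(vocabulary)) stopf("an RSM needs a vocabulary (rownames or `vocabulary`)")
  vocabulary <- as.character(vocabulary)
  if (length(vocabulary) != nrow(mat)) stopf("vocabulary length does not match matrix size")
  if (anyDuplicated(vocabulary)) stopf("duplicate words in RSM vocabulary")
  dimnames(mat) <- list(vocabulary, vocabulary)
  out <- structure(mat, class = c("rsm", "matrix", "array"), source = source)
  if (validate) validate_rsm(out)
  out
}

validate_rsm <- function(x) {
  m <- unclass(x)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-10) stopf("RSM is not symmetric (max |m - t(m)| = %.3g)", asym)
  if (grepl("^corpus decade|^cosine", rsm_source(x))) {
    if (max(abs(diag(m) - 1)) > 1e-10) stopf("cosine RSM must have a unit diagonal")
    if (min(m) < -1 - 1e-10 || max(m) > 1 + 1e-10)
      stopf("cosine RSM values must lie in [-1, 1]")
  }
  invisible(x)
}

#' @rdname new_rsm
#' @param x an `rsm`.
#' @export
rsm_source <- function(x) attr(x, "source") %||% "unknown"

#' @rdname new_rsm
#' @export
rsm_vocabulary <- function(x) rownames(x)

#' @export
print.rsm <- function(x, ...) {
  v <- nrow(x)
  cat(sprintf("RSM: %d words, source: %s\n", v, rsm_source(x)))
  k <- min(5L, v)
  print(round(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], 3))
  if (v > k) cat(sprintf("... (%d more rows/columns)\n", v - k))
  invisible(x)
}

#' Extract the off-diagonal upper triangle of an RSM
#'
#' Returns the cells (i, j) with i < j in row-major order, the canonical
#' vectorization used for all RSA comparisons.  The matrix must be symmetric
#' to within 1e-8.
#'
#' @param rsm an `rsm` or symmetric matrix.
#' @return numeric vector of length `v * (v - 1) / 2`.
#' @export
upper_triangle_values <- function(rsm) {
  m <- unclass(as.matrix(rsm))
  if (nrow(m) != ncol(m)) stopf("matrix must be square")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) stopf("matrix is asymmetric beyond 1e-8 (max deviation %.3g)", asym)
  # lower triangle of the transpose, column-major == upper triangle, row-major
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Restrict an RSM to a subset of its vocabulary
#'
#' @param x an `rsm`.
#' @param words character vector of words to keep; the result preserves the
#'   order given here.
#' @export
rsm_subset <- function(x, words) {
  missing <- setdiff(words, rsm_vocabulary(x))
  if (length(missing))
    stopf("words not in RSM vocabulary: %s", paste(utils::head(missing, 5), collapse = ", "))
  new_rsm(unclass(x)[words, words, drop = FALSE], words, source = rsm_source(x),
          validate = FALSE)
}

#' Read and write RSMs as TSV
#'
#' The TSV layout has the vocabulary as both a header row and a first column.
#' `write_rsm_tsv()` can also drop a small JSON sidecar (same path plus
#' `.json`) recording the vocabulary and source tag.
#'
#' @param x an `rsm`.
#' @param path file path of the TSV.
#' @param sidecar also write `<path>.json` with vocabulary and source.
#' @export
write_rsm_tsv <- function(x, path, sidecar = FALSE) {
  df <- data.frame(word = rsm_vocabulary(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(vocabulary = rsm_vocabulary(x), source = rsm_source(x)),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_rsm_tsv
#' @param source source tag to attach on read (the TSV itself stores only
#'   values; if a JSON sidecar exists it supplies the tag).
#' @export
read_rsm_tsv <- function(path, source = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vocab <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  side <- paste0(path, ".json")
  if (is.null(source) && file.exists(side)) {
    source <- jsonlite::read_json(side)$source
  }
  new_rsm(m, vocab, source = source %||% "unknown", validate = FALSE)
}

# symmetric cellwise Gaussian noise with the diagonal reset to 1;
# used by the cohort/hypothesis simulators
add_symmetric_noise <- function(m, sd) {
  if (sd <= 0) return(m)
  v <- nrow(m)
  e <- matrix(0, v, v)
  e[upper.tri(e)] <- stats::rnorm(v * (v - 1) / 2, sd = sd)
  e <- e + t(e)
  out <- unclass(m) + e
  diag(out) <- 1
  out
}
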