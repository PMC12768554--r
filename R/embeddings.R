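#' Per-decade word embeddings
#'
#' A `decade_embeddings` object holds one decade's word-vector matrix: a year
#' label, an ordered vocabulary with no duplicates, and a numeric matrix with
#' one row per word.  Zero-norm rows are legal on construction (some corpora
#' contain them) but are flagged with a warning and rejected by similarity
#' computations, where the cosine is undefined.
#'
#' @param decade integer year label (e.g. 1950).
#' @param vocabulary character vector of unique words, in row order.
#' @param vectors numeric matrix, `length(vocabulary)` rows.
#' @return an object of class `decade_embeddings` with fields `decade`,
#'   `vocabulary`, `vectors` and a logical `zero_norm` flag per word.
#' @export
decade_embeddings <- function(decade, vocabulary, vectors) {
  vocabulary <- as.character(vocabulary)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (anyDuplicated(vocabulary)) {
    dup <- unique(vocabulary[duplicated(vocabulary)])
    stopf("duplicate words in vocabulary: %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (nrow(vectors) != length(vocabulary))
    stopf("vocabulary has %d words but vectors has %d rows",
          length(vocabulary), nrow(vectors))
  if (anyNA(vectors)) stopf("embedding matrix contains NA values")
  rownames(vectors) <- vocabulary
  zero <- sqrt(rowSums(vectors^2)) == 0
  if (any(zero))
    warnf("%d zero-norm vector(s) flagged and excluded from similarity computations: %s",
          sum(zero), paste(utils::head(vocabulary[zero], 5), collapse = ", "))
  structure(
    list(decade = as.integer(decade), vocabulary = vocabulary,
         vectors = vectors, zero_norm = zero),
    class = "decade_embeddings")
}

#' @export
print.decade_embeddings <- function(x, ...) {
  cat(sprintf("decade_embeddings: decade %s, %d words, dimension %d\n",
              x$decade, length(x$vocabulary), ncol(x$vectors)))
  invisible(x)
}

#' @export
dim.decade_embeddings <- function(x) dim(x$vectors)

#' Read and write word2vec text files
#'
#' The word2vec text dialect: an optional header line `"n d"` followed by one
#' line per word, `"word v1 ... vd"`.  File word order is preserved; duplicate
#' words and ragged rows are errors.  `write_word2vec_text()` uses 17
#' significant digits so a write/read round trip reproduces the values
#' exactly.
#'
#' @param path file path.
#' @param decade year label to attach to the result (the format itself does
#'   not carry one).
#' @return `load_word2vec_text()` returns a [decade_embeddings()] object.
#' @export
load_word2vec_text <- function(path, decade = NA_integer_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty word2vec file: %s", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  first <- toks[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  offset <- if (has_header) 1L else 0L
  body <- toks[(offset + 1L):length(toks)]
  if (!length(body)) stopf("word2vec file has a header but no vectors: %s", path)
  d <- length(body[[1]]) - 1L
  if (d < 1L) stopf("format error at line %d: no vector values", offset + 1L)
  words <- character(length(body))
  mat <- matrix(NA_real_, length(body), d)
  for (i in seq_along(body)) {
    tk <- body[[i]]
    if (length(tk) - 1L != d)
      stopf("format error at line %d: expected %d values, got %d",
            i + offset, d, length(tk) - 1L)
    vals <- suppressWarnings(as.numeric(tk[-1]))
    if (anyNA(vals))
      stopf("format error at line %d: non-numeric vector entry", i + offset)
    words[i] <- tk[1]
    mat[i, ] <- vals
  }
  if (has_header) {
    n_declared <- as.integer(first[1])
    if (!is.na(n_declared) && n_declared != length(words))
      warnf("header declares %d words but file has %d", n_declared, length(words))
  }
  decade_embeddings(decade, words, mat)
}

#' @rdname load_word2vec_text
#' @param emb a [decade_embeddings()] object.
#' @param header write the `"n d"` header line.
#' @export
write_word2vec_text <- function(emb, path, header = TRUE) {
  stopifnot(inherits(emb, "decade_embeddings"))
  rows <- vapply(seq_along(emb$vocabulary), function(i) {
    paste(emb$vocabulary[i],
          paste(sprintf("%.17g", emb$vectors[i, ]), collapse = " "))
  }, character(1))
  if (header) rows <- c(sprintf("%d %d", nrow(emb$vectors), ncol(emb$vectors)), rows)
  writeLines(rows, path)
  invisible(path)
}

#' An aligned (or alignable) series of decade embeddings
#'
#' Groups several [decade_embeddings()] over an identical vocabulary ordering.
#' `aligned` is `TRUE` only once every decade has been mapped into the
#' reference decade's space (either by [align_series()] or because the series
#' was generated in a common frame).
#'
#' @param decades named list of `decade_embeddings` (names are year labels),
#'   all sharing vocabulary order and dimension.
#' @param aligned logical.
#' @param reference_decade year label of the alignment anchor.
#' @export
aligned_series <- function(decades, aligned = FALSE, reference_decade = NA_integer_) {
  stopifnot(length(decades) >= 1L,
            all(vapply(decades, inherits, logical(1), "decade_embeddings")))
  vocab <- decades[[1]]$vocabulary
  d <- ncol(decades[[1]]$vectors)
  for (e in decades) {
    if (!identical(e$vocabulary, vocab))
      stopf("all decades in a series must share an identical vocabulary ordering")
    if (ncol(e$vectors) != d)
      stopf("all decades in a series must share one embedding dimension")
  }
  names(decades) <- vapply(decades, function(e) as.character(e$decade), character(1))
  structure(
    list(decades = decades, aligned = isTRUE(aligned),
         reference_decade = as.integer(reference_decade)),
    class = "aligned_series")
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("aligned_series: %d decades (%s), %d words, %s\n",
              length(x$decades), paste(names(x$decades), collapse = ", "),
              length(x$decades[[1]]$vocabulary),
              if (x$aligned) sprintf("aligned to %s", x$reference_decade) else "unaligned"))
  invisible(x)
}

series_decades <- function(series) as.integer(names(series$decades))

get_decade <- function(series, decade) {
  key <- as.character(decade)
  if (!key %in% names(series$decades))
    stopf("decade %s not in series (have: %s)", key,
          paste(names(series$decades), collapse = ", "))
  series$decades[[key]]
}

#' Restrict decade embeddings to a shared vocabulary
#'
#' Intersects the vocabularies of all provided decades (optionally further
#' intersected with `extra`), sorts the result lexicographically, and
#' restricts every decade to that ordering.  Lexicographic order makes the
#' downstream upper-triangle extraction deterministic.
#'
#' @param series a list of [decade_embeddings()] or an [aligned_series()].
#' @param extra optional character vector to intersect with additionally
#'   (e.g. the cue vocabulary of an association dataset).
#' @return an unaligned [aligned_series()] over the shared vocabulary.
#' @export
intersect_vocabulary <- function(series, extra = NULL) {
  if (inherits(series, "aligned_series")) series <- series$decades
  if (inherits(series, "decade_embeddings")) series <- list(series)
  if (!length(series)) stopf("at least one decade is required")
  shared <- Reduce(intersect, lapply(series, function(e) e$vocabulary))
  if (!is.null(extra)) shared <- intersect(shared, as.character(extra))
  # C-locale sort: stable across platforms/locales
  shared <- stringSort(shared)
  if (!length(shared)) stopf("empty vocabulary intersection")
  restricted <- lapply(series, function(e) {
    suppressWarnings(decade_embeddings(e$decade, shared,
                                       e$vectors[shared, , drop = FALSE]))
  })
  aligned_series(restricted, aligned = FALSE)
}

stringSort <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Orthogonal Procrustes alignment of one decade onto another
#'
#' Finds the orthogonal matrix `R` minimizing the Frobenius distance
#' `||source %*% R - target||_F` (closed form: `R = U V'` from the SVD of
#' `source' target`) and returns the rotation together with the rotated
#' embeddings.  Both inputs must share vocabulary order and dimension.
#'
#' @param source,target [decade_embeddings()] with identical vocabulary order.
#' @return list with `rotation` (orthogonal `d x d` matrix), `aligned`
#'   (rotated `decade_embeddings` for the source decade) and `residual`
#'   (Frobenius distance to the target after rotation).
#' @export
procrustes_align <- function(source, target) {
  stopifnot(inherits(source, "decade_embeddings"), inherits(target, "decade_embeddings"))
  if (!identical(source$vocabulary, target$vocabulary))
    stopf("source and target must share an identical vocabulary ordering")
  if (ncol(source$vectors) != ncol(target$vectors))
    stopf("source and target must share one embedding dimension")
  s <- svd(crossprod(source$vectors, target$vectors))
  rotation <- s$u %*% t(s$v)
  rotated <- source$vectors %*% rotation
  aligned <- suppressWarnings(decade_embeddings(source$decade, source$vocabulary, rotated))
  list(rotation = rotation, aligned = aligned,
       residual = sqrt(sum((rotated - target$vectors)^2)))
}

#' Align every decade of a series to a reference decade
#'
#' Each decade is mapped directly onto the reference decade (default: the
#' latest) by [procrustes_align()], rather than chained decade-to-decade,
#' so all pairs of decades remain directly comparable and alignment error
#' does not accumulate.
#'
#' @param series an [aligned_series()] (typically from
#'   [intersect_vocabulary()]).
#' @param reference year label of the anchor decade; default latest.
#' @return the series with every decade rotated into the reference frame and
#'   `aligned = TRUE`.
#' @export
align_series <- function(series, reference = NULL) {
  stopifnot(inherits(series, "aligned_series"))
  decades <- series_decades(series)
  reference <- as.integer(reference %||% max(decades))
  ref_emb <- get_decade(series, reference)
  out <- lapply(series$decades, function(e) {
    if (e$decade == reference) e else procrustes_align(e, ref_emb)$aligned
  })
  aligned_series(out, aligned = TRUE, reference_decade = reference)
}

#' Cosine similarity RSM from one decade's embeddings
#'
#' Stored vectors are never re-normalized in place; normalization happens
#' inside the cosine so the source vectors keep their file values.
#'
#' @param emb a [decade_embeddings()] object.
#' @param subset optional word list (must be in the vocabulary); defaults to
#'   the full vocabulary.
#' @param source override the source tag (default `"corpus decade <year>"`).
#' @return an [new_rsm()] with unit diagonal and values in `[-1, 1]`.
#' @export
cosine_rsm <- function(emb, subset = NULL, source = NULL) {
  stopifnot(inherits(emb, "decade_embeddings"))
  subset <- subset %||% emb$vocabulary
  missing <- setdiff(subset, emb$vocabulary)
  if (length(missing))
    stopf("subset words not in vocabulary: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  v <- emb$vectors[subset, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0))
    stopf("zero-norm vector(s), cosine undefined for: %s",
          paste(utils::head(subset[nrm == 0], 5), collapse = ", "))
  vn <- v / nrm
  s <- tcrossprod(vn)
  s <- (s + t(s)) / 2
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  new_rsm(s, subset, source = source %||% sprintf("corpus decade %s", emb$decade))
}

#' Decade RSMs for a whole series
#'
#' Convenience wrapper applying [cosine_rsm()] to every decade.
#'
#' @inheritParams align_series
#' @param subset optional shared word subset.
#' @return named list of RSMs, names are the year labels in series order.
#' @export
decade_rsms <- function(series, subset = NULL) {
  stopifnot(inherits(series, "aligned_series"))
  lapply(series$decades, cosine_rsm, subset = subset)
}

#' Cross-decade self-similarity of a single word
#'
#' The cosine between one word's vectors in two decades of an aligned series;
#' the basic measure of how much that word's meaning moved.  Requires an
#' aligned series: comparing vectors across unaligned spaces is meaningless.
#'
#' @inheritParams align_series
#' @param word word present in both decades.
#' @param t1,t2 decade labels.
#' @return cosine similarity (scalar).
#' @export
self_similarity <- function(series, word, t1, t2) {
  stopifnot(inherits(series, "aligned_series"))
  if (!series$aligned)
    stopf("series is not aligned; align first (see align_series())")
  e1 <- get_decade(series, t1)
  e2 <- get_decade(series, t2)
  if (!word %in% e1$vocabulary || !word %in% e2$vocabulary)
    stopf("word '%s' missing from decade %s or %s", word, t1, t2)
  a <- e1$vectors[word, ]
  b <- e2$vectors[word, ]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("zero-norm vector for word '%s'", word)
  min(1, max(-1, sum(a * b) / (na * nb)))
}
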