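# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All seeded entry points route
# through this so that a given seed is reproducible regardless of the
# surrounding RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

# per-session cache (drift calibrations)
.chronolex_cache <- new.env(parent = emptyenv())

# unit-normalize matrix rows; zero rows are left untouched
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x)

# sample() without the scalar-numeric surprise
shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

# sequential softmax sampling without replacement; the max logit is
# re-subtracted before each draw so the distribution stays well defined even
# in the near-deterministic low-temperature limit
sample_softmax <- function(items, logits, k) {
  out <- character(k)
  avail <- seq_along(items)
  for (j in seq_len(k)) {
    w <- exp(logits[avail] - max(logits[avail]))
    pick <- avail[sample.int(length(avail), 1L, prob = w)]
    out[j] <- items[pick]
    avail <- setdiff(avail, pick)
  }
  out
}
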