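# internal helpers shared across modules

# Deterministic 31-bit seed derived from a master seed and an artifact tag.
# Each output artifact gets its own RNG stream so that adding artifacts never
# perturbs existing ones.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647 + 1)
}

# Evaluate expr with its own RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop(sprintf("'%s' must be a single non-negative integer, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample n elements from a vector without the scalar-x pitfall of sample()
sample_from <- function(x, n) x[sample.int(length(x), n)]

# overlapsAny with harmonized seqlevels (avoids cross-object warnings)
overlaps_any <- function(query, subject, maxgap = -1L) {
  lv <- union(GenomeInfoDb::seqlevels(query),
              GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  IRanges::overlapsAny(query, subject, maxgap = maxgap,
                       ignore.strand = TRUE)
}
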