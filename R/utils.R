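## Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, kept within 32-bit range.
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9176) %% 2147483587) + 1L
}

checkScalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must lie in [%s, %s] (got %s)", name,
                 format(min), format(max), format(x)), call. = FALSE)
  if (integer && x != floor(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# "chr:start-end" identifiers in the 0-based half-open convention used for
# feature ids and BED output.
binIdOf <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

variantKey <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}
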