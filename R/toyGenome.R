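#' Build a toy genome for synthetic cohorts
#'
#' Creates a small autosome-like genome: `nChrom` chromosomes of `chromLen`
#' bp, per-bin GC fractions drawn from a truncated normal centered near the
#' genome-wide average GC of 0.41, and (optionally) one contiguous masked
#' region per chromosome covering approximately `maskFraction` of its length,
#' standing in for a repeat mask.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLen chromosome length in bp (>= `binSize`). Either a single
#'   length shared by all chromosomes or a vector of length `nChrom`.
#' @param binSize native bin width in bp at which GC is drawn (default 5 Mb).
#' @param maskFraction fraction of each chromosome covered by the mask, in
#'   \[0,1\].
#' @param seed integer seed; the genome is deterministic given the seed.
#' @param gcMean,gcSd location and spread of the per-bin GC distribution;
#'   draws are clamped to \[0.25, 0.65\].
#' @return A [ToyGenome].
#' @examples
#' g <- buildToyGenome(nChrom = 2, chromLen = 12e6, binSize = 5e6,
#'                     maskFraction = 0, seed = 1)
#' @export
buildToyGenome <- function(nChrom, chromLen, binSize = 5e6, maskFraction = 0,
                           seed = 1, gcMean = 0.41, gcSd = 0.04) {
  checkScalar(nChrom, "nChrom", min = 1, integer = TRUE)
  checkScalar(binSize, "binSize", min = 1)
  checkScalar(maskFraction, "maskFraction", min = 0, max = 1)
  if (any(chromLen <= 0)) stop("'chromLen' must be positive", call. = FALSE)
  if (any(chromLen < binSize))
    stop("'chromLen' must be >= 'binSize'", call. = FALSE)
  lens <- rep_len(chromLen, nChrom)
  names(lens) <- paste0("chr", seq_len(nChrom))

  withSeed(seed, {
    nb <- floor(lens / binSize)
    bins <- GRanges(rep(names(lens), nb),
                    IRanges(start = unlist(lapply(nb, function(k)
                      (seq_len(k) - 1) * binSize + 1), use.names = FALSE),
                      width = binSize))
    GenomeInfoDb::seqlevels(bins) <- names(lens)
    gc <- pmin(0.65, pmax(0.25, stats::rnorm(length(bins), gcMean, gcSd)))
    mcols(bins)$gc <- gc
    mask <- GRanges()
    if (maskFraction > 0) {
      mw <- round(maskFraction * lens)
      off <- floor(stats::runif(nChrom) * (lens - mw))
      keep <- mw > 0
      if (any(keep))
        mask <- GRanges(names(lens)[keep],
                        IRanges(start = off[keep] + 1, width = mw[keep]))
    }
    gn <- new("ToyGenome", chromLengths = lens, binSize = binSize,
              gcBins = bins, mask = mask)
    validObject(gn)
    gn
  })
}

#' Total genome size of a toy genome
#' @param genome a [ToyGenome].
#' @param unmasked if `TRUE` (default) subtract masked bases.
#' @return Size in bp.
#' @export
genomeSize <- function(genome, unmasked = TRUE) {
  tot <- sum(genome@chromLengths)
  if (unmasked && length(genome@mask))
    tot <- tot - sum(width(GenomicRanges::reduce(genome@mask)))
  tot
}
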