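#' Construct a fragment size-class scheme
#'
#' The default scheme defines ShortPeak1 = 100–150 bp, LongPeak1 = 151–220
#' bp, ShortPeak2 = 221–300 bp and LongPeak2 = 311–400 bp (inclusive bounds).
#' The 301–310 bp gap between peak-2 classes is intentional: fragments there
#' count toward per-bin totals but belong to no class.
#'
#' @param labels class labels.
#' @param lower,upper inclusive bp bounds per class.
#' @return A [SizeClassScheme].
#' @export
sizeClassScheme <- function(labels = c("SP1", "LP1", "SP2", "LP2"),
                            lower = c(100, 151, 221, 311),
                            upper = c(150, 220, 300, 400)) {
  new("SizeClassScheme", labels = labels, lower = lower, upper = upper)
}

#' Classify fragment lengths into size classes
#'
#' Pure function mapping each length to the unique inclusive range containing
#' it, or `NA` when the length falls outside all ranges (shorter than the
#' first class, longer than the last, or in an inter-class gap).
#'
#' @param length numeric vector of fragment lengths in bp (positive).
#' @param scheme a [SizeClassScheme].
#' @return Factor with the scheme's labels as levels; `NA` for unclassified
#'   lengths.
#' @examples
#' classifySize(c(120, 167, 305, 400, 401), sizeClassScheme())
#' @export
classifySize <- function(length, scheme = sizeClassScheme()) {
  if (any(length <= 0)) stop("'length' must be positive", call. = FALSE)
  out <- rep(NA_integer_, length(length))
  for (k in seq_along(scheme@labels)) {
    out[length >= scheme@lower[k] & length <= scheme@upper[k]] <- k
  }
  factor(scheme@labels[out], levels = scheme@labels)
}

#' Load cfDNA fragments from a BED file or coordinate-sorted BAM
#'
#' For BED input each row (0-based half-open) becomes one fragment. For BAM
#' input one fragment is formed per properly paired, primary, non-duplicate
#' read pair with mapping quality at least `minMapq`, spanning the leftmost
#' 5' end to the rightmost 5' end of the pair (the template length).
#' Non-autosomal records are excluded, and exclusion counts are recorded in
#' the provenance.
#'
#' @param path path to a `.bed` (BED3) or `.bam` file.
#' @param minMapq minimum mapping quality for BAM records (default 30).
#' @param autosomes character vector of chromosomes to retain.
#' @param sampleId,timepoint labels attached to the resulting set.
#' @return A [FragmentSet], coordinate-sorted.
#' @export
loadFragments <- function(path, minMapq = 30,
                          autosomes = paste0("chr", 1:22),
                          sampleId = basename(path), timepoint = "landmark") {
  if (!length(autosomes)) stop("'autosomes' must be non-empty", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read fragment input '%s'", path), call. = FALSE)
  isBam <- grepl("\\.bam$", path, ignore.case = TRUE)
  if (isBam) {
    flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE, isMinusStrand = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag,
                                     what = c("rname", "pos", "isize", "mapq"))
    rec <- Rsamtools::scanBam(path, param = param)[[1]]
    nIn <- length(rec$pos)
    ok <- !is.na(rec$isize) & rec$isize > 0 & !is.na(rec$mapq) &
      rec$mapq >= minMapq
    chrom <- as.character(rec$rname)[ok]
    onAuto <- chrom %in% autosomes
    nMapq <- sum(!ok, na.rm = TRUE)
    nChrom <- sum(!onAuto)
    gr <- GRanges(chrom[onAuto],
                  IRanges(start = rec$pos[ok][onAuto],
                          width = rec$isize[ok][onAuto]))
    excluded <- c(lowMapqOrUnpaired = nMapq, nonAutosomal = nChrom)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    mcols(gr) <- NULL
    nIn <- length(gr)
    onAuto <- as.character(seqnames(gr)) %in% autosomes
    excluded <- c(lowMapqOrUnpaired = 0L, nonAutosomal = sum(!onAuto))
    gr <- gr[onAuto]
  }
  if (length(gr) == 0L)
    stop(sprintf("no fragments survive ingestion of '%s'", path), call. = FALSE)
  gr <- GenomeInfoDb::keepSeqlevels(gr, intersect(autosomes, seqlevels(gr)),
                                    pruning.mode = "coarse")
  gr <- sort(gr)
  new("FragmentSet", fragments = gr, sampleId = sampleId,
      timepoint = timepoint,
      provenance = list(source = path, minMapq = minMapq,
                        recordsSeen = nIn, excluded = as.list(excluded),
                        downsamplingFactor = 1))
}

#' Write a fragment set as BED3 (plus a JSON provenance sidecar)
#'
#' @param fs a [FragmentSet].
#' @param path output `.bed` path; `<path>.json` receives the provenance.
#' @return `path`, invisibly.
#' @export
writeFragmentsBed <- function(fs, path) {
  gr <- fs@fragments
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    c(list(sampleId = fs@sampleId, timepoint = fs@timepoint), fs@provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Downsample a fragment set to a target base coverage
#'
#' Observed coverage is total fragment bases over `genomeSize`. When it
#' already lies at or below `targetCoverage` the input is returned unchanged
#' with factor 1; otherwise each fragment is independently retained with
#' probability `targetCoverage / observed` (seeded binomial thinning), which
#' preserves the fragment-length distribution in expectation. This mirrors
#' the unification of heterogeneous WGS depths to a common working coverage
#' before feature extraction.
#'
#' @param fs a [FragmentSet].
#' @param targetCoverage target fold coverage (> 0), e.g. 5.
#' @param genomeSize effective (unmasked autosomal) genome size in bp.
#' @param seed integer seed.
#' @return A [FragmentSet] with the applied factor recorded in provenance.
#' @export
downsampleToCoverage <- function(fs, targetCoverage, genomeSize, seed = 1) {
  checkScalar(targetCoverage, "targetCoverage", min = 1e-12)
  checkScalar(genomeSize, "genomeSize", min = 1)
  observed <- sum(as.numeric(width(fs@fragments))) / genomeSize
  if (observed <= targetCoverage) {
    fs@provenance$downsamplingFactor <- 1
    fs@provenance$observedCoverage <- observed
    return(fs)
  }
  p <- targetCoverage / observed
  keep <- withSeed(seed, stats::runif(length(fs@fragments)) < p)
  fs@fragments <- fs@fragments[keep]
  fs@provenance$downsamplingFactor <- p
  fs@provenance$observedCoverage <- observed
  fs@provenance$downsampleSeed <- seed
  fs
}
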