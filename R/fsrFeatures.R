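#' Tile a genome into fixed-width bins for FSR profiling
#'
#' Per chromosome, consecutive full-width bins `[0, binSize)`,
#' `[binSize, 2 binSize)`, ... are created; trailing partial bins are
#' dropped. A bin is flagged masked when its overlap with the genome's mask
#' exceeds `maskThreshold` of its width. GC per bin is aggregated from the
#' genome's native per-bin GC (overlap-weighted when bin widths differ).
#' On the human autosomes with a repeat mask this construction yields the
#' 541 5-Mb bins whose 4 features each give the 2,164-feature FSR profile.
#'
#' @param genome a [ToyGenome].
#' @param binSize bin width in bp (defaults to the genome's native width).
#' @param maskThreshold mask-overlap fraction above which a bin is excluded
#'   (default 0.5).
#' @return A [BinSet].
#' @export
makeBins <- function(genome, binSize = genome@binSize, maskThreshold = 0.5) {
  checkScalar(binSize, "binSize", min = 1)
  checkScalar(maskThreshold, "maskThreshold", min = 0, max = 1)
  lens <- genome@chromLengths
  nb <- floor(lens / binSize)
  if (sum(nb) == 0)
    stop("bin construction produced an empty bin set", call. = FALSE)
  bins <- GRanges(rep(names(lens), nb),
                  IRanges(start = unlist(lapply(nb, function(k)
                    (seq_len(k) - 1) * binSize + 1), use.names = FALSE),
                    width = binSize))
  GenomeInfoDb::seqlevels(bins) <- names(lens)
  bins <- sort(bins)

  ## overlap-weighted GC from the genome's native bins
  src <- genome@gcBins
  hits <- findOverlaps(bins, src)
  ov <- width(pintersect(bins[queryHits(hits)], src[subjectHits(hits)]))
  gcNum <- tapply(ov * src$gc[subjectHits(hits)], queryHits(hits), sum)
  gcDen <- tapply(ov, queryHits(hits), sum)
  gc <- rep(mean(src$gc), length(bins))
  gc[as.integer(names(gcNum))] <- as.numeric(gcNum / gcDen)
  mcols(bins)$gc <- gc

  masked <- rep(FALSE, length(bins))
  if (length(genome@mask)) {
    mk <- GenomicRanges::reduce(genome@mask)
    hits <- findOverlaps(bins, mk)
    ov <- width(pintersect(bins[queryHits(hits)], mk[subjectHits(hits)]))
    cov <- tapply(ov, queryHits(hits), sum)
    masked[as.integer(names(cov))] <- as.numeric(cov) > maskThreshold * binSize
  }
  mcols(bins)$masked <- masked
  new("BinSet", bins = bins, binSize = binSize)
}

#' Tally fragments per bin and size class
#'
#' Each fragment is assigned to the bin containing its leftmost coordinate;
#' fragments falling in masked bins, outside all bins, or outside the
#' scheme's overall length range are ignored. Returns per-class counts plus
#' a per-bin total over all in-range fragments (the total includes fragments
#' in inter-class gaps, so it can exceed the class sum).
#'
#' @param fs a [FragmentSet].
#' @param bins a [BinSet] from the same genome.
#' @param scheme a [SizeClassScheme].
#' @return A [BinCounts] over the unmasked bins.
#' @export
countByBin <- function(fs, bins, scheme = sizeClassScheme()) {
  b <- bins@bins[!bins@bins$masked]
  if (length(b) == 0L) stop("no unmasked bins", call. = FALSE)
  fr <- fs@fragments
  starts <- GenomicRanges::resize(fr, width = 1L, fix = "start")
  hits <- findOverlaps(starts, b, select = "first")
  len <- width(fr)
  inRange <- len >= min(scheme@lower) & len <= max(scheme@upper)
  keep <- !is.na(hits) & inRange
  cls <- classifySize(pmax(len, 1L), scheme)
  K <- length(scheme@labels)
  nb <- length(b)
  counts <- matrix(0L, nb, K, dimnames = list(NULL, scheme@labels))
  tb <- table(factor(hits[keep & !is.na(cls)], levels = seq_len(nb)),
              cls[keep & !is.na(cls)])
  counts[, colnames(tb)] <- as.integer(tb)
  total <- as.numeric(table(factor(hits[keep], levels = seq_len(nb))))
  new("BinCounts", counts = counts, total = total, binIds = binIdOf(b))
}

#' Compute the (uncorrected) FSR profile from bin counts
#'
#' Per bin, four features: the fraction of the sample's genome-wide
#' fragments of each size class falling in that bin (the class's spatial
#' profile; each non-empty class sums to 1 across bins). The per-bin
#' short/long count ratios for both peaks are attached as a diagnostic
#' channel, with a pseudocount of 1 on the denominator to guard sparse bins.
#'
#' @param counts a [BinCounts].
#' @param sampleId label carried into the profile.
#' @return An [FSRProfile] (not yet GC-corrected).
#' @export
computeFSR <- function(counts, sampleId = "sample") {
  cts <- counts@counts
  if (sum(cts) + sum(counts@total) == 0)
    stop("no fragments genome-wide; cannot form an FSR profile", call. = FALSE)
  classes <- colnames(cts)
  nb <- nrow(cts)
  prof <- matrix(0, nb, length(classes), dimnames = list(NULL, classes))
  for (k in classes) {
    tot <- sum(cts[, k])
    if (tot == 0) {
      warning(sprintf("size class %s is empty genome-wide; features set to 0", k))
    } else {
      prof[, k] <- cts[, k] / tot
    }
  }
  feat <- as.numeric(t(prof))  # bin-major: all 4 classes of bin 1, then bin 2, ...
  names(feat) <- paste(rep(counts@binIds, each = length(classes)), classes,
                       sep = "|")
  ratios <- cbind(peak1 = cts[, 1] / (cts[, 2] + 1),
                  peak2 = cts[, 3] / (cts[, 4] + 1))
  new("FSRProfile", sampleId = sampleId, features = feat, ratios = ratios,
      binIds = counts@binIds, classes = classes, gcCorrected = FALSE)
}

# Projection-based GC smoother: natural cubic spline regression of feature
# value on bin GC. Being an orthogonal projection (with intercept), residuals
# have exactly zero mean and re-correction is exactly idempotent.
gcSmoothResiduals <- function(y, gc, df) {
  df <- min(df, length(unique(gc)) - 2L)
  if (length(y) < 8L || df < 1L) return(NULL)
  basis <- splines::ns(gc, df = df)
  stats::lm.fit(cbind(1, basis), y)$residuals
}

#' Remove GC-content coverage bias from an FSR profile
#'
#' For each of the four per-class spatial profiles independently, a smooth
#' trend of feature value on bin GC fraction is fitted (natural cubic spline
#' regression, `df` degrees of freedom) and removed; the corrected value is
#' the residual plus the class mean. The correction is per-sample, exactly
#' mean-preserving, and exactly idempotent (the smoother is a projection).
#' With too few bins to support the smoother the profile is returned with a
#' mean-only (identity) correction and a warning.
#'
#' @param profile an [FSRProfile].
#' @param bins the [BinSet] the profile was computed on.
#' @param df smoother flexibility (spline degrees of freedom, default 6).
#' @return A GC-corrected [FSRProfile].
#' @export
gcCorrect <- function(profile, bins, df = 6) {
  b <- bins@bins[!bins@bins$masked]
  ids <- binIdOf(b)
  if (!identical(ids, profile@binIds))
    stop("profile and bin set disagree on the unmasked bins", call. = FALSE)
  gc <- b$gc
  classes <- profile@classes
  K <- length(classes)
  nb <- length(ids)
  feat <- profile@features
  for (k in seq_len(K)) {
    idx <- seq(k, by = K, length.out = nb)
    y <- feat[idx]
    r <- gcSmoothResiduals(y, gc, df)
    if (is.null(r)) {
      warning("too few bins for the GC smoother; mean-only correction applied")
      next
    }
    feat[idx] <- r + mean(y)
  }
  new("FSRProfile", sampleId = profile@sampleId, features = feat,
      ratios = profile@ratios, binIds = profile@binIds,
      classes = classes, gcCorrected = TRUE)
}

#' Extract the full FSR profile of one fragment set
#'
#' Convenience wrapper chaining [countByBin()], [computeFSR()] and
#' (optionally) [gcCorrect()].
#'
#' @param fs a [FragmentSet].
#' @param bins a [BinSet].
#' @param scheme a [SizeClassScheme].
#' @param correctGC apply GC correction (default TRUE).
#' @param df smoother flexibility passed to [gcCorrect()].
#' @return An [FSRProfile].
#' @export
fsrProfile <- function(fs, bins, scheme = sizeClassScheme(), correctGC = TRUE,
                       df = 6) {
  p <- computeFSR(countByBin(fs, bins, scheme), sampleId = fs@sampleId)
  if (correctGC) p <- gcCorrect(p, bins, df = df)
  p
}

#' Assemble per-sample FSR profiles into a feature matrix
#'
#' @param profiles list of [FSRProfile] sharing one bin set and scheme.
#' @param standardize fit per-feature z-score parameters (requires >= 2
#'   samples); the parameters are stored for reuse on held-out samples, and
#'   the stored matrix itself remains unstandardized.
#' @return An [FSRMatrix] (samples x features).
#' @export
assembleMatrix <- function(profiles, standardize = FALSE) {
  ids <- vapply(profiles, function(p) p@sampleId, "")
  lens <- vapply(profiles, function(p) length(p@features), 0L)
  if (length(unique(lens)) != 1L)
    stop("inconsistent feature lengths for samples: ",
         paste(ids[lens != stats::median(lens)], collapse = ", "),
         call. = FALSE)
  featNames <- names(profiles[[1]]@features)
  x <- do.call(rbind, lapply(profiles, function(p) {
    if (!identical(names(p@features), featNames))
      stop("feature ordering differs for sample ", p@sampleId, call. = FALSE)
    p@features
  }))
  rownames(x) <- ids
  center <- numeric(0); scale <- numeric(0)
  if (standardize) {
    if (nrow(x) < 2L)
      stop("standardization requires at least 2 samples", call. = FALSE)
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  new("FSRMatrix", x = x, center = center, scale = scale)
}

#' Write a feature matrix as TSV (with JSON metadata sidecar)
#'
#' @param fm an [FSRMatrix].
#' @param path output `.tsv` path; `<path>.json` receives metadata.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  df <- data.frame(sample = rownames(fm@x), fm@x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(nSamples = nrow(fm@x), nFeatures = ncol(fm@x),
                            standardized = length(fm@center) > 0),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#' @param path `.tsv` path.
#' @return An [FSRMatrix].
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  new("FSRMatrix", x = x, center = numeric(0), scale = numeric(0))
}
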