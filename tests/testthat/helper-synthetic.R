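# Shared fixture builders (all generated in code; no stored data).

toyGenome2x12 <- function(seed = 1, maskFraction = 0) {
  buildToyGenome(nChrom = 2, chromLen = 12e6, binSize = 5e6,
                 maskFraction = maskFraction, seed = seed)
}

# Genome sized for model experiments: 4 x 30 Mb -> 24 bins, 96 features.
modelGenome <- function(seed = 1) {
  buildToyGenome(nChrom = 4, chromLen = 3e7, binSize = 5e6, seed = seed)
}

# FragmentSet built directly from vectors (chrom, 0-based start, length).
makeFragmentSet <- function(chrom, start0, len, sampleId = "S1",
                            seqlevels = unique(chrom)) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, width = len))
  GenomeInfoDb::seqlevels(gr) <- seqlevels
  new("FragmentSet", fragments = sort(gr), sampleId = sampleId,
      timepoint = "landmark",
      provenance = list(downsamplingFactor = 1))
}

# Outcome-independent noise features with a cohort-shaped outcome table.
nullCohortData <- function(n = 87, p = 96, nEvents = 23, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n),
                              sprintf("f%03d", 1:p)))
  ev <- c(rep(1, nEvents), rep(0, n - nEvents))
  tt <- ifelse(ev == 1, round(runif(n, 100, 950)), round(runif(n, 600, 1259)))
  list(x = x, outcomes = data.frame(time_days = tt, event = ev))
}

# End-to-end signal cohort: simulate, extract GC-corrected FSR features.
signalCohortFeatures <- function(seed, nPatients = 87,
                                 recurrenceFraction = 23 / 87,
                                 fragmentsPerSample = 2e5, genome = NULL) {
  if (is.null(genome)) genome <- modelGenome(seed)
  coh <- simulateCohort(nPatients, recurrenceFraction, thetaHigh = 0.05,
                        thetaLow = 0, fragmentsPerSample = fragmentsPerSample,
                        genome = genome, seed = seed,
                        timepoints = "landmark")
  bins <- makeBins(genome)
  profiles <- lapply(coh, function(p) fsrProfile(p@fragments, bins))
  list(cohort = coh, bins = bins,
       features = assembleMatrix(profiles),
       clinical = clinicalTable(coh))
}

# Brute-force per-fragment bin/class tally, independent of countByBin.
bruteForceCounts <- function(fs, bins, scheme = sizeClassScheme()) {
  b <- binRanges(bins)[!binRanges(bins)$masked]
  gr <- granges(fs)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  len <- GenomicRanges::width(gr)
  bChrom <- as.character(GenomicRanges::seqnames(b))
  bStart <- GenomicRanges::start(b); bEnd <- GenomicRanges::end(b)
  K <- length(scheme@labels)
  counts <- matrix(0L, length(b), K, dimnames = list(NULL, scheme@labels))
  total <- numeric(length(b))
  for (i in seq_along(gr)) {
    j <- which(bChrom == chrom[i] & bStart <= pos[i] & bEnd >= pos[i])
    if (length(j) != 1L) next
    if (len[i] < min(scheme@lower) || len[i] > max(scheme@upper)) next
    total[j] <- total[j] + 1
    for (k in seq_len(K)) {
      if (len[i] >= scheme@lower[k] && len[i] <= scheme@upper[k]) {
        counts[j, k] <- counts[j, k] + 1L
        break
      }
    }
  }
  list(counts = counts, total = total)
}

# Exhaustive cutoff search, independent of selectCutoff.
bruteForceCutoff <- function(scores, labels, minSpec) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)])
  best <- NULL
  for (t in cand) {
    sens <- sum(scores > t & labels == 1) / sum(labels == 1)
    spec <- sum(scores <= t & labels == 0) / sum(labels == 0)
    if (spec < minSpec) next
    if (is.null(best) || sens > best$sens ||
        (sens == best$sens && spec > best$spec) ||
        (sens == best$sens && spec == best$spec && t > best$t))
      best <- list(t = t, sens = sens, spec = spec)
  }
  best
}

# Pair-counting AUC oracle.
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Direct binomial upper-tail sum oracle on the log scale.
tailSumOracle <- function(alt, depth, rate) {
  if (alt <= 0) return(1)
  k <- alt:depth
  sum(exp(lchoose(depth, k) + k * log(rate) + (depth - k) * log1p(-rate)))
}
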