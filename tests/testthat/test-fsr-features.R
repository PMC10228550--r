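test_that("bin construction drops partial bins, aggregates GC and applies the mask threshold", {
  g <- toyGenome2x12(seed = 1)
  b <- makeBins(g)
  expect_equal(length(binRanges(b)), 4L)
  expect_equal(gcContent(b), gcContent(g))

  ## mask covering 60% of bin 1 -> flagged at threshold 0.5; 40% -> not
  g@mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e6))
  b <- makeBins(g, maskThreshold = 0.5)
  expect_true(binRanges(b)$masked[1])
  expect_false(any(binRanges(b)$masked[-1]))
  g@mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e6))
  b <- makeBins(g, maskThreshold = 0.5)
  expect_false(any(binRanges(b)$masked))

  tiny <- buildToyGenome(1, 6e6, binSize = 5e6, seed = 1)
  expect_error(makeBins(tiny, binSize = 7e6), "empty bin set")
})

test_that("fragments are assigned to bins by leftmost coordinate", {
  g <- toyGenome2x12(seed = 1)
  b <- makeBins(g)
  ## leftmost coordinate 4,999,990 (0-based) < 5,000,000 -> bin 1
  fs <- makeFragmentSet("chr1", 4999990, 170, seqlevels = c("chr1", "chr2"))
  ct <- countByBin(fs, b)
  expect_equal(ct@total, c(1, 0, 0, 0))
  expect_equal(unname(ct@counts[1, "LP1"]), 1L)

  fs2 <- makeFragmentSet(rep("chr1", 1000), seq(0, 999) * 400, rep(120, 1000),
                         seqlevels = c("chr1", "chr2"))
  ct2 <- countByBin(fs2, b)
  expect_equal(unname(ct2@counts[1, "SP1"]), 1000L)
  expect_equal(sum(ct2@counts) - 1000L, 0L)
})

test_that("bin counting equals a brute-force per-fragment scan", {
  g <- buildToyGenome(3, 11e6, binSize = 2e6, maskFraction = 0.2, seed = 4)
  b <- makeBins(g)
  set.seed(10)
  n <- 1e4
  chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
  start0 <- sample.int(109e5, n, replace = TRUE)
  len <- sample(c(80:450), n, replace = TRUE)
  fs <- makeFragmentSet(chrom, start0, len, seqlevels = paste0("chr", 1:3))
  got <- countByBin(fs, b)
  want <- bruteForceCounts(fs, b)
  expect_equal(unname(got@counts), unname(want$counts))
  expect_equal(got@total, want$total)
})

test_that("FSR features are per-class spatial fractions with diagnostic ratios", {
  g <- toyGenome2x12(seed = 1)
  b <- makeBins(g)
  ## every fragment in bin 3 (chr2 first bin)
  lens <- rep(c(120, 170, 250, 350), each = 50)
  fs <- makeFragmentSet(rep("chr2", 200), seq_len(200) * 1000, lens,
                        seqlevels = c("chr1", "chr2"))
  prof <- computeFSR(countByBin(fs, b))
  f <- featureValues(prof)
  expect_length(f, 16L)
  binOf <- rep(1:4, each = 4)
  expect_equal(unname(f[binOf == 3]), rep(1, 4))
  expect_equal(unname(f[binOf != 3]), rep(0, 12))

  ## per-class conservation on a scattered sample
  set.seed(2)
  fs2 <- makeFragmentSet(sample(c("chr1", "chr2"), 5000, TRUE),
                         sample.int(9e6, 5000, TRUE),
                         sample(100:400, 5000, TRUE),
                         seqlevels = c("chr1", "chr2"))
  prof2 <- computeFSR(countByBin(fs2, b))
  m <- matrix(featureValues(prof2), ncol = 4, byrow = TRUE)
  expect_equal(unname(colSums(m)), rep(1, 4))
  expect_true(all(featureValues(prof2) >= 0))

  ## empty class genome-wide -> zeros with a warning
  fs3 <- makeFragmentSet(rep("chr1", 100), seq_len(100) * 100, rep(167, 100),
                         seqlevels = c("chr1", "chr2"))
  expect_warning(p3 <- computeFSR(countByBin(fs3, b)), "empty genome-wide")
  m3 <- matrix(featureValues(p3), ncol = 4, byrow = TRUE)
  expect_equal(unname(colSums(m3)[c(1, 3, 4)]), rep(0, 3))

  ## SP1-enriched bins show a higher short/long diagnostic ratio
  enriched <- makeFragmentSet(
    c(rep("chr1", 400), rep("chr2", 200)),
    c(seq_len(400) * 1000, seq_len(200) * 1000),
    c(rep(120, 300), rep(170, 100), rep(c(120, 170), 100)),
    seqlevels = c("chr1", "chr2"))
  flat <- makeFragmentSet(
    c(rep("chr1", 200), rep("chr2", 200)),
    c(seq_len(200) * 1000, seq_len(200) * 1000),
    rep(c(120, 170), 200), seqlevels = c("chr1", "chr2"))
  rEnr <- computeFSR(countByBin(enriched, b))@ratios[1, "peak1"]
  rFlat <- computeFSR(countByBin(flat, b))@ratios[1, "peak1"]
  expect_gt(rEnr, rFlat)
})

test_that("matrix assembly enforces the 4-per-bin feature contract", {
  g3 <- buildToyGenome(1, 16e6, binSize = 5e6, seed = 2)  # 3 bins
  b3 <- makeBins(g3)
  set.seed(3)
  profs <- lapply(1:3, function(i) {
    fs <- makeFragmentSet(rep("chr1", 2000), sample.int(15e6, 2000, TRUE),
                          sample(100:400, 2000, TRUE), sampleId = paste0("S", i),
                          seqlevels = "chr1")
    computeFSR(countByBin(fs, b3), sampleId = paste0("S", i))
  })
  fm <- assembleMatrix(profs, standardize = TRUE)
  expect_equal(dim(featureMatrix(fm)), c(3L, 12L))
  expect_length(fm@center, 12L)

  expect_error(assembleMatrix(profs[1], standardize = TRUE), "at least 2")

  short <- profs
  short[[2]]@features <- short[[2]]@features[1:8]
  short[[2]]@binIds <- short[[2]]@binIds[1:2]
  expect_error(assembleMatrix(short), "S2")
})

test_that("GC correction removes an injected exponential GC bias and is exactly idempotent", {
  g <- buildToyGenome(4, 75e6, binSize = 5e6, seed = 6)  # 60 bins
  b <- makeBins(g)
  gc <- gcContent(b)
  nb <- length(gc)
  rs <- vapply(1:10, function(s) {
    set.seed(s)
    base <- 1 / nb
    biased <- base * exp(2 * (gc - 0.41)) * (1 + rnorm(nb, 0, 0.05))
    feats <- as.numeric(t(matrix(rep(biased / sum(biased), 4), nb, 4)))
    names(feats) <- paste(rep(binIds(b), each = 4),
                          c("SP1", "LP1", "SP2", "LP2"), sep = "|")
    prof <- new("FSRProfile", sampleId = "S", features = feats,
                ratios = matrix(0, nb, 2), binIds = binIds(b),
                classes = c("SP1", "LP1", "SP2", "LP2"), gcCorrected = FALSE)
    corr <- gcCorrect(prof, b)
    m <- matrix(featureValues(corr), ncol = 4, byrow = TRUE)
    ## mean preserved exactly per class
    raw <- matrix(featureValues(prof), ncol = 4, byrow = TRUE)
    expect_equal(colMeans(m), colMeans(raw), tolerance = 1e-12)
    ## idempotent to well below 1e-6 relative
    again <- gcCorrect(corr, b)
    expect_lt(max(abs(featureValues(again) - featureValues(corr))) /
                max(abs(featureValues(corr))), 1e-9)
    abs(cor(m[, 1], gc))
  }, 0)
  expect_true(all(rs < 0.1))

  ## constant profile is untouched
  constFeats <- rep(1 / nb, 4 * nb)
  names(constFeats) <- paste(rep(binIds(b), each = 4),
                             c("SP1", "LP1", "SP2", "LP2"), sep = "|")
  constProf <- new("FSRProfile", sampleId = "S", features = constFeats,
                   ratios = matrix(0, nb, 2), binIds = binIds(b),
                   classes = c("SP1", "LP1", "SP2", "LP2"),
                   gcCorrected = FALSE)
  out <- gcCorrect(constProf, b)
  expect_lt(max(abs(featureValues(out) - constFeats)), 1e-6 / nb)

  ## too few bins -> mean-only fallback with warning
  g2 <- toyGenome2x12(seed = 1)
  b2 <- makeBins(g2)
  fs <- makeFragmentSet(rep("chr1", 500), seq_len(500) * 1000,
                        sample(100:400, 500, TRUE),
                        seqlevels = c("chr1", "chr2"))
  p <- computeFSR(countByBin(fs, b2))
  expect_warning(gcCorrect(p, b2), "mean-only")
})
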