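test_that("fragment length mixture has the mononucleosomal mode and shifts short with tumor fraction", {
  len0 <- sampleFragmentLengths(1e5, theta = 0, seed = 11)
  tb <- table(len0)
  mode0 <- as.integer(names(tb)[which.max(tb)])
  expect_lte(abs(mode0 - 167), 3)

  cfg <- lengthMixtureConfig()
  len1 <- sampleFragmentLengths(1e5, theta = 1, cfg = cfg, seed = 11)
  tb1 <- table(len1)
  mode1 <- as.integer(names(tb1)[which.max(tb1)])
  expect_lte(abs(mode1 - cfg@tumorMode), 3)

  means <- vapply(seq(0, 1, by = 0.1), function(th)
    mean(sampleFragmentLengths(1e5, th, seed = 7)), 0)
  expect_true(all(diff(means) < 0))
  expect_true(all(len0 >= cfg@range[1] & len0 <= cfg@range[2]))
})

test_that("generators are bit-identical under a fixed seed and reject bad parameters", {
  expect_identical(sampleFragmentLengths(5000, 0.3, seed = 42),
                   sampleFragmentLengths(5000, 0.3, seed = 42))
  expect_error(sampleFragmentLengths(100, theta = 1.2, seed = 1), "theta")
  expect_error(sampleFragmentLengths(0, theta = 0, seed = 1), "n")

  g1 <- toyGenome2x12(seed = 5, maskFraction = 0.1)
  g2 <- toyGenome2x12(seed = 5, maskFraction = 0.1)
  expect_identical(gcContent(g1), gcContent(g2))

  coh1 <- simulateCohort(4, 0.5, 0.05, 0, fragmentsPerSample = 2000,
                         genome = g1, seed = 3, timepoints = "landmark")
  coh2 <- simulateCohort(4, 0.5, 0.05, 0, fragmentsPerSample = 2000,
                         genome = g1, seed = 3, timepoints = "landmark")
  expect_identical(granges(coh1[[1]]@fragments), granges(coh2[[1]]@fragments))
  expect_identical(clinicalTable(coh1), clinicalTable(coh2))

  expect_error(buildToyGenome(0, 1e7, seed = 1), "nChrom")
  expect_error(buildToyGenome(2, -5, seed = 1), "chromLen")
  expect_error(buildToyGenome(2, 1e6, binSize = 5e6, seed = 1), "chromLen")
})

test_that("toy genome respects bin arithmetic, GC bounds and masking", {
  g <- toyGenome2x12(seed = 1)
  expect_equal(length(binRanges(g)), 4L)  # floor(12/5) = 2 per chromosome
  expect_true(all(gcContent(g) >= 0 & gcContent(g) <= 1))

  gm <- toyGenome2x12(seed = 1, maskFraction = 1)
  bins <- makeBins(gm)
  expect_true(all(binRanges(bins)$masked))

  gh <- toyGenome2x12(seed = 2, maskFraction = 0.3)
  mask <- gh@mask
  expect_true(all(GenomicRanges::end(mask) <=
                    gh@chromLengths[as.character(GenomicRanges::seqnames(mask))]))
})

test_that("cohort event counts and proportional hazards match the generative model", {
  g <- toyGenome2x12(seed = 1)
  events <- vapply(1:5, function(s) {
    coh <- simulateCohort(87, 23 / 87, 0.05, 0, fragmentsPerSample = 200,
                          genome = g, seed = s, timepoints = "landmark")
    sum(clinicalTable(coh)$event)
  }, 0)
  expect_gt(mean(events), 17)
  expect_lt(mean(events), 29)

  ## PH recovery: log HR between groups should track hazardCoefficient * dtheta
  hc <- 20; dtheta <- 0.05  # true log HR = 1
  z <- replicate(20, NA_real_); lhr <- replicate(20, NA_real_)
  for (s in 1:20) {
    coh <- simulateCohort(80, 0.5, thetaHigh = 0.05, thetaLow = 0,
                          hazardCoefficient = hc, fragmentsPerSample = 100,
                          genome = g, seed = 100 + s, timepoints = "landmark",
                          baselineHazard = 1.5e-3)
    clin <- clinicalTable(coh)
    grp <- vapply(coh, function(p) p@theta > 0.025, TRUE)
    hr <- coxHR(factor(ifelse(grp, "high", "low"), levels = c("low", "high")),
                clin)
    lhr[s] <- log(hr$hr)
  }
  se <- sd(lhr) / sqrt(20)
  expect_lt(abs(mean(lhr) - hc * dtheta), 3 * se + 0.15)
})

test_that("variant tables carry the constructed categories and binomial VAFs", {
  g <- toyGenome2x12(seed = 1)
  coh <- simulateCohort(2, 0.5, 0.1, 0, fragmentsPerSample = 500, genome = g,
                        seed = 9, timepoints = "landmark")
  pHigh <- coh[[1]]  # first patient carries thetaHigh
  expect_gt(tumorFraction(pHigh), 0.05)
  pZero <- coh[[2]]
  expect_equal(tumorFraction(pZero), 0)

  vt0 <- simulateVariantTable(pZero, nTrue = 5, nChip = 3, nLeuko = 2,
                              seed = 1)
  expect_true(all(vt0$alt_reads[vt0$in_tissue & !vt0$in_blacklist &
                                  vt0$leukocyte_alt_reads == 0] == 0))
  expect_equal(sum(vt0$in_blacklist), 3L)
  expect_true(all(vt0$leukocyte_alt_reads[vt0$in_blacklist |
                                            !vt0$in_tissue] >= 0))
  leukoRows <- which(!vt0$in_blacklist & vt0$in_tissue &
                       vt0$leukocyte_alt_reads >= 1)
  expect_equal(length(leukoRows), 2L)

  ## mean VAF of true variants ~ theta / 2
  pHigh@theta <- 0.1
  vafs <- unlist(lapply(1:20, function(s) {
    vt <- simulateVariantTable(pHigh, nTrue = 10, nChip = 0, nLeuko = 0,
                               depth = 1000, seed = s)
    vt$vaf
  }))
  expect_lt(abs(mean(vafs) - 0.05), 0.003)
})
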