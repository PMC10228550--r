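## Synthetic cohort generation: fragments + survival outcomes + variant
## tables with the statistical structure the downstream analysis assumes.

# Sample fragment positions for one sample on the current RNG stream.
# Healthy-derived fragments are uniform over bins up to a GC coverage bias
# exp(gcBiasCoef * (gc - 0.41)); tumor-derived fragments are additionally
# enriched `tumorEnrichment`-fold in the genome's fixed tumor-shedding bins,
# giving the regionally distinct fragmentation profile seen in progressing
# patients.
drawFragments <- function(n, theta, genome, cfg, gcBiasCoef, tumorBins,
                          tumorEnrichment) {
  bins <- genome@gcBins
  isTumorFrag <- stats::runif(n) < theta
  len <- drawLengths(n, theta, cfg, component = isTumorFrag)
  wH <- exp(gcBiasCoef * (bins$gc - 0.41))
  wT <- wH * ifelse(seq_along(bins) %in% tumorBins, tumorEnrichment, 1)
  idx <- integer(n)
  nh <- sum(!isTumorFrag)
  if (nh) idx[!isTumorFrag] <- sample.int(length(bins), nh, replace = TRUE, prob = wH)
  nt <- sum(isTumorFrag)
  if (nt) idx[isTumorFrag] <- sample.int(length(bins), nt, replace = TRUE, prob = wT)
  binStart <- start(bins)[idx]
  chrom <- as.character(seqnames(bins))[idx]
  chromLen <- genome@chromLengths[chrom]
  st <- binStart + floor(stats::runif(n) * genome@binSize)
  st <- pmin(st, chromLen - len)  # keep the fragment inside the chromosome
  st <- pmax(st, 1)
  gr <- GRanges(chrom, IRanges(start = st, width = len))
  GenomeInfoDb::seqlevels(gr) <- names(genome@chromLengths)
  sort(gr)
}

#' Simulate a synthetic patient cohort
#'
#' Generates per-patient tumor fractions, survival outcomes, clinical
#' covariates and cfDNA fragment sets with the structure the MRD analysis
#' assumes: patients destined to recur carry tumor fractions near
#' `thetaHigh`, the rest near `thetaLow`; event times are exponential with
#' log-hazard `hazardCoefficient * theta` over a baseline, censored uniformly
#' over the follow-up window; fragment lengths follow the
#' [lengthMixtureConfig()] mixture at the sample's tumor fraction; fragment
#' positions carry a GC coverage bias plus a tumor-bin enrichment (see
#' Details).
#'
#' @details A fixed, seeded subset of bins (`tumorBinFraction` of the genome)
#' is designated tumor-shedding: tumor-derived fragments are
#' `tumorEnrichment`-fold enriched there, so higher tumor fractions shift the
#' per-bin spatial profile of short fragments — the signal the FSR features
#' are designed to read out. For non-recurrence patients the longitudinal
#' tumor fraction decays by `thetaDecay`.
#'
#' @param nPatients cohort size.
#' @param recurrenceFraction fraction of patients assigned the high tumor
#'   fraction (strictly between 0 and 1).
#' @param thetaHigh,thetaLow tumor fractions of the two groups
#'   (`thetaHigh > thetaLow >= 0`).
#' @param hazardCoefficient log-hazard slope on tumor fraction; 0 gives a
#'   null cohort whose outcomes are independent of the fragmentomics signal.
#' @param fragmentsPerSample fragments drawn per sample.
#' @param genome a [ToyGenome].
#' @param seed integer seed; output is bit-identical across runs.
#' @param timepoints subset of `c("landmark", "longitudinal")` to simulate.
#' @param baselineHazard baseline event rate per day at theta = 0.
#' @param followupDays censoring window (uniform over \[0, followupDays\]).
#' @param gcBiasCoef GC coverage bias coefficient `b` in
#'   `exp(b * (gc - 0.41))`.
#' @param tumorEnrichment,tumorBinFraction tumor-bin spatial enrichment
#'   (fold) and the fraction of bins designated tumor-shedding.
#' @param thetaDecay multiplier on the longitudinal tumor fraction of
#'   non-recurrence patients.
#' @param cfg a [LengthMixtureConfig].
#' @return List of [SyntheticPatient] (one per patient and timepoint), with
#'   attribute `"tumorBins"` recording the enriched bin indices.
#' @examples
#' g <- buildToyGenome(2, 12e6, 5e6, seed = 1)
#' coh <- simulateCohort(6, 0.5, 0.05, 0, fragmentsPerSample = 2000,
#'                       genome = g, seed = 1, timepoints = "landmark")
#' @export
simulateCohort <- function(nPatients, recurrenceFraction, thetaHigh, thetaLow,
                           hazardCoefficient = 100, fragmentsPerSample = 2e5,
                           genome, seed, timepoints = c("landmark", "longitudinal"),
                           baselineHazard = 5e-5, followupDays = 1259,
                           gcBiasCoef = 2, tumorEnrichment = 3,
                           tumorBinFraction = 0.2, thetaDecay = 0.1,
                           cfg = lengthMixtureConfig()) {
  checkScalar(nPatients, "nPatients", min = 1, integer = TRUE)
  checkScalar(recurrenceFraction, "recurrenceFraction", min = 0, max = 1)
  if (recurrenceFraction <= 0 || recurrenceFraction >= 1)
    stop("'recurrenceFraction' must lie strictly between 0 and 1", call. = FALSE)
  if (!(thetaHigh > thetaLow) || thetaLow < 0)
    stop("'thetaHigh' must exceed 'thetaLow' and 'thetaLow' must be >= 0",
         call. = FALSE)
  timepoints <- match.arg(timepoints, c("landmark", "longitudinal"),
                          several.ok = TRUE)
  nBins <- length(genome@gcBins)
  if (fragmentsPerSample < nBins)
    warning("fragmentsPerSample is too small to populate every bin; ",
            "sparse bins will carry zero counts")

  withSeed(seed, {
    nRec <- round(nPatients * recurrenceFraction)
    highGroup <- seq_len(nPatients) <= nRec
    jitter <- stats::runif(nPatients, 0.8, 1.2)
    theta <- ifelse(highGroup, pmin(1, thetaHigh * jitter),
                    pmin(1, thetaLow * jitter))
    rate <- baselineHazard * exp(hazardCoefficient * theta)
    tEvent <- stats::rexp(nPatients, rate)
    tCens <- stats::runif(nPatients, 0, followupDays)
    time <- pmax(1, ceiling(pmin(tEvent, tCens)))
    event <- as.integer(tEvent <= tCens)

    clin <- data.frame(
      patient_id = sprintf("P%03d", seq_len(nPatients)),
      age = round(stats::runif(nPatients, 42, 79)),
      sex = sample(c("male", "female"), nPatients, TRUE, prob = c(0.53, 0.47)),
      stage = sample(c("I", "II", "III"), nPatients, TRUE,
                     prob = c(42, 14, 31) / 87),
      smoking = sample(c("yes", "no"), nPatients, TRUE, prob = c(0.18, 0.82)),
      histology = sample(c("adenocarcinoma", "squamous", "other"), nPatients,
                         TRUE, prob = c(0.83, 0.13, 0.04)),
      adjuvant = sample(c("yes", "no"), nPatients, TRUE, prob = c(0.4, 0.6)),
      stringsAsFactors = FALSE
    )

    tumorBins <- sample.int(nBins, max(1L, round(tumorBinFraction * nBins)))

    patients <- list()
    for (i in seq_len(nPatients)) {
      out <- cbind(data.frame(time_days = time[i], event = event[i]),
                   clin[i, -1, drop = FALSE])
      for (tp in timepoints) {
        th <- theta[i]
        if (tp == "longitudinal" && !highGroup[i]) th <- th * thetaDecay
        fr <- drawFragments(fragmentsPerSample, th, genome, cfg, gcBiasCoef,
                            tumorBins, tumorEnrichment)
        fs <- new("FragmentSet", fragments = fr,
                  sampleId = clin$patient_id[i], timepoint = tp,
                  provenance = list(source = "simulateCohort", seed = seed,
                                    downsamplingFactor = 1))
        patients[[length(patients) + 1L]] <- new("SyntheticPatient",
          patientId = clin$patient_id[i], theta = th, timepoint = tp,
          fragments = fs, outcome = out,
          variants = data.frame())
      }
    }
    attr(patients, "tumorBins") <- tumorBins
    patients
  })
}

#' Clinical table of a simulated cohort
#'
#' @param patients list of [SyntheticPatient] from [simulateCohort()].
#' @return `data.frame` with one row per patient sample: `patient_id`,
#'   `timepoint`, `event`, `time_days` and the clinical covariates.
#' @export
clinicalTable <- function(patients) {
  do.call(rbind, lapply(patients, function(p) {
    cbind(data.frame(patient_id = p@patientId, timepoint = p@timepoint,
                     stringsAsFactors = FALSE), p@outcome)
  }))
}

#' Simulate a tumor-informed variant table for one patient sample
#'
#' Emulates the inputs of tumor-informed ctDNA tracking: `nTrue` genuine
#' tumor variants (alt reads binomial with success probability theta/2, i.e.
#' expected VAF half the tumor fraction for heterozygous clonal variants),
#' `nChip` clonal hematopoiesis variants present on the blacklist, and
#' `nLeuko` artifacts supported by at least one read in the paired leukocyte
#' control.
#'
#' @param patient a [SyntheticPatient].
#' @param nTrue,nChip,nLeuko row counts per category.
#' @param depth sequencing depth per site (>= 1).
#' @param seed integer seed.
#' @param chipVafRange VAF range of CHIP variants.
#' @param leukoRate per-read artifact rate used for leukocyte-supported rows.
#' @return `data.frame` with columns `patient_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `alt_reads`, `depth`, `vaf`, `in_tissue`, `in_blacklist`,
#'   `leukocyte_alt_reads`.
#' @export
simulateVariantTable <- function(patient, nTrue = 10, nChip = 3, nLeuko = 3,
                                 depth = 1000, seed = 1,
                                 chipVafRange = c(0.01, 0.05),
                                 leukoRate = 5e-4) {
  checkScalar(depth, "depth", min = 1, integer = TRUE)
  theta <- patient@theta
  withSeed(seed, {
    n <- nTrue + nChip + nLeuko
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    df <- data.frame(
      patient_id = patient@patientId,
      chrom = paste0("chr", sample.int(22, n, TRUE)),
      pos = sample.int(2e8, n),
      ref = ref, alt = alt,
      alt_reads = 0L, depth = as.integer(depth), vaf = 0,
      in_tissue = rep(c(TRUE, FALSE, TRUE), c(nTrue, nChip, nLeuko)),
      in_blacklist = rep(c(FALSE, TRUE, FALSE), c(nTrue, nChip, nLeuko)),
      leukocyte_alt_reads = 0L,
      stringsAsFactors = FALSE
    )
    if (nTrue) df$alt_reads[seq_len(nTrue)] <-
      stats::rbinom(nTrue, depth, theta / 2)
    if (nChip) {
      p <- stats::runif(nChip, chipVafRange[1], chipVafRange[2])
      idx <- nTrue + seq_len(nChip)
      df$alt_reads[idx] <- stats::rbinom(nChip, depth, p)
      df$leukocyte_alt_reads[idx] <- stats::rbinom(nChip, depth, p)
    }
    if (nLeuko) {
      idx <- nTrue + nChip + seq_len(nLeuko)
      df$alt_reads[idx] <- stats::rbinom(nLeuko, depth, leukoRate)
      df$leukocyte_alt_reads[idx] <- 1L + stats::rbinom(nLeuko, depth, leukoRate)
    }
    df$vaf <- df$alt_reads / df$depth
    df
  })
}
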