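#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlevels keepSeqlevels
NULL

#' Fragment length mixture configuration
#'
#' Parameterizes the cfDNA fragment-length model used by the synthetic cohort
#' generator: a healthy two-component mixture (mononucleosomal peak near
#' 167 bp plus a dinucleosomal peak near 334 bp) and a shorter tumor-derived
#' component. Lengths are drawn from
#' \eqn{(1-\theta)\,f_{healthy} + \theta\,f_{tumor}} where \eqn{\theta} is the
#' sample tumor fraction, then truncated to the admissible range.
#'
#' @slot healthyModes numeric(2), modes (bp) of the mono- and dinucleosomal
#'   healthy components.
#' @slot healthySds numeric(2), standard deviations (bp) of those components.
#' @slot healthyWeights numeric(2), mixture weights of the healthy components;
#'   must sum to 1.
#' @slot tumorMode,tumorSd numeric(1), mode and spread (bp) of the tumor
#'   component.
#' @slot range numeric(2), admissible fragment length range (bp), inclusive.
#' @export
setClass("LengthMixtureConfig",
  representation(
    healthyModes = "numeric", healthySds = "numeric",
    healthyWeights = "numeric", tumorMode = "numeric", tumorSd = "numeric",
    range = "numeric"
  )
)

setValidity("LengthMixtureConfig", function(object) {
  msg <- character()
  if (length(object@healthyModes) != 2L || length(object@healthySds) != 2L ||
      length(object@healthyWeights) != 2L)
    msg <- c(msg, "healthyModes, healthySds, healthyWeights must have length 2")
  if (any(object@healthyWeights < 0) || any(object@healthyWeights > 1) ||
      abs(sum(object@healthyWeights) - 1) > 1e-8)
    msg <- c(msg, "healthyWeights must lie in [0,1] and sum to 1")
  if (length(object@range) != 2L || object@range[1] >= object@range[2])
    msg <- c(msg, "range must be an increasing pair")
  modes <- c(object@healthyModes, object@tumorMode)
  if (any(modes < object@range[1] | modes > object@range[2]))
    msg <- c(msg, "all modes must lie within the admissible range")
  if (any(c(object@healthySds, object@tumorSd) <= 0))
    msg <- c(msg, "spreads must be positive")
  if (length(msg)) msg else TRUE
})

#' Toy genome for synthetic cohorts
#'
#' A small stand-in reference genome: autosome-like chromosomes with per-bin
#' GC fractions and optional masked (excluded) regions. It plays the role the
#' reference assembly and repeat mask play for real data.
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot binSize numeric(1), the native bin width (bp) at which GC was drawn.
#' @slot gcBins [GenomicRanges::GRanges] of full-width bins with metadata
#'   column `gc` (fraction in \[0,1\]).
#' @slot mask [GenomicRanges::GRanges] of regions excluded from analysis.
#' @export
setClass("ToyGenome",
  representation(chromLengths = "numeric", binSize = "numeric",
                 gcBins = "GRanges", mask = "GRanges")
)

setValidity("ToyGenome", function(object) {
  msg <- character()
  if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
    msg <- c(msg, "chromLengths must be named and positive")
  gc <- object@gcBins$gc
  if (is.null(gc) || any(gc < 0 | gc > 1))
    msg <- c(msg, "gcBins must carry a gc column in [0,1]")
  if (length(object@mask)) {
    lens <- object@chromLengths[as.character(seqnames(object@mask))]
    if (any(is.na(lens)) || any(end(object@mask) > lens) ||
        any(start(object@mask) < 1))
      msg <- c(msg, "mask intervals must lie within chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' A set of cfDNA fragments from one sample
#'
#' One sequenced cfDNA molecule is an interval on a chromosome; its length is
#' the distance between the 5' ends of the read pair (end minus start in the
#' 0-based half-open convention). Fragments are kept coordinate-sorted, with
#' provenance (source, filters, downsampling factor, seed) attached.
#'
#' @slot fragments [GenomicRanges::GRanges], coordinate-sorted.
#' @slot sampleId character(1) sample identifier.
#' @slot timepoint character(1), e.g. `"landmark"` or `"longitudinal"`.
#' @slot provenance list of ingestion/processing metadata.
#' @export
setClass("FragmentSet",
  representation(fragments = "GRanges", sampleId = "character",
                 timepoint = "character", provenance = "list")
)

setValidity("FragmentSet", function(object) {
  fr <- object@fragments
  if (length(fr) && any(width(fr) <= 0)) return("fragment widths must be positive")
  if (S4Vectors::isSorted(fr) == FALSE) return("fragments must be coordinate-sorted")
  ds <- object@provenance$downsamplingFactor
  if (!is.null(ds) && (ds <= 0 || ds > 1))
    return("downsampling factor must lie in (0, 1]")
  TRUE
})

#' Fragment size-class scheme
#'
#' Four labeled inclusive bp ranges around the mono- and dinucleosomal peaks:
#' ShortPeak1 (100–150), LongPeak1 (151–220), ShortPeak2 (221–300) and
#' LongPeak2 (311–400) by default. Note the default scheme deliberately leaves
#' 301–310 bp unassigned; fragments there count toward bin totals but belong
#' to no class.
#'
#' @slot labels character(4) class labels.
#' @slot lower,upper numeric(4) inclusive bounds in bp.
#' @export
setClass("SizeClassScheme",
  representation(labels = "character", lower = "numeric", upper = "numeric")
)

setValidity("SizeClassScheme", function(object) {
  k <- length(object@labels)
  if (length(object@lower) != k || length(object@upper) != k)
    return("labels, lower, upper must have equal length")
  if (any(object@lower > object@upper)) return("each lower bound must be <= upper")
  o <- order(object@lower)
  if (any(object@lower[o][-1] <= object@upper[o][-k]))
    return("ranges must not overlap")
  TRUE
})

#' Genomic bin set for FSR profiling
#'
#' Consecutive full-width bins per chromosome (default 5 Mb), each with its GC
#' fraction and a masked flag; masked bins are excluded from feature output.
#'
#' @slot bins [GenomicRanges::GRanges] with metadata columns `gc` and `masked`.
#' @slot binSize numeric(1) bin width in bp.
#' @export
setClass("BinSet", representation(bins = "GRanges", binSize = "numeric"))

setValidity("BinSet", function(object) {
  b <- object@bins
  if (!all(c("gc", "masked") %in% names(mcols(b))))
    return("bins must carry gc and masked columns")
  if (length(b) && any(width(b) != object@binSize))
    return("only full-width bins may be retained")
  if (!S4Vectors::isSorted(b)) return("bins must be sorted")
  TRUE
})

#' Per-bin size-class fragment tallies
#'
#' @slot counts integer matrix, unmasked bins x size classes.
#' @slot total integer vector, all in-range fragments per bin (including
#'   fragments falling in inter-class gaps).
#' @slot binIds character, bin identifiers ("chr:start-end", 0-based
#'   half-open) matching the rows.
#' @export
setClass("BinCounts",
  representation(counts = "matrix", total = "numeric", binIds = "character")
)

#' Fragment size ratio (FSR) profile of one sample
#'
#' Per sample, four features per unmasked bin: the fraction of the sample's
#' genome-wide fragments of each size class that falls in the bin (each
#' class's spatial profile, summing to 1 across bins when the class is
#' non-empty). The short/long count ratios per peak are kept as a diagnostic
#' channel with a pseudocount of 1 on the denominator.
#'
#' @slot sampleId character(1).
#' @slot features named numeric of length 4 x bins, bin-major ordering
#'   ("chr:start-end|CLASS").
#' @slot ratios numeric matrix bins x 2 (`peak1`, `peak2` short/long ratios).
#' @slot binIds character bin identifiers.
#' @slot classes character(4) class labels in feature order.
#' @slot gcCorrected logical(1).
#' @export
setClass("FSRProfile",
  representation(sampleId = "character", features = "numeric",
                 ratios = "matrix", binIds = "character",
                 classes = "character", gcCorrected = "logical")
)

setValidity("FSRProfile", function(object) {
  if (length(object@features) != 4L * length(object@binIds))
    return("feature vector length must equal 4 x number of bins")
  if (any(!is.finite(object@features))) return("all features must be finite")
  TRUE
})

#' Sample-by-feature FSR matrix
#'
#' @slot x numeric matrix, samples (rows) x features (columns).
#' @slot center,scale per-feature standardization parameters (length 0 until
#'   fitted).
#' @export
setClass("FSRMatrix",
  representation(x = "matrix", center = "numeric", scale = "numeric")
)

setValidity("FSRMatrix", function(object) {
  if (anyNA(object@x)) return("feature matrix must not contain missing values")
  for (s in c("center", "scale")) {
    v <- slot(object, s)
    if (length(v) && length(v) != ncol(object@x))
      return(sprintf("%s length must match feature count", s))
  }
  TRUE
})

#' Fitted elastic-net penalized Cox model
#'
#' @slot coefficients named numeric over features.
#' @slot l1Ratio numeric(1) elastic-net mixing parameter in \[0,1\].
#' @slot penalty numeric(1) selected penalty strength (lambda).
#' @slot center,scale standardization applied to features before fitting.
#' @export
setClass("CoxnetFit",
  representation(coefficients = "numeric", l1Ratio = "numeric",
                 penalty = "numeric", center = "numeric", scale = "numeric")
)

setValidity("CoxnetFit", function(object) {
  if (object@penalty < 0) return("penalty must be >= 0")
  TRUE
})

#' Leave-one-out cross-validated risk scores
#'
#' One risk score per sample, each produced by a model whose training set
#' excluded that sample.
#'
#' @slot scores data.frame with columns `sample`, `score`, `fold`,
#'   `timepoint`, `flagged` (TRUE when the training fold had no events and the
#'   score defaulted to 0).
#' @export
setClass("RiskScoreSet", representation(scores = "data.frame"))

setValidity("RiskScoreSet", function(object) {
  need <- c("sample", "score", "fold", "timepoint", "flagged")
  if (!all(need %in% names(object@scores)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@scores$sample)) return("one score per sample")
  TRUE
})

#' Specificity-constrained risk-score cutoff
#'
#' @slot threshold numeric(1); samples with score strictly above it are called
#'   high risk.
#' @slot sensitivity,specificity achieved operating point on the score set.
#' @slot roc data.frame of ROC points (threshold, sensitivity, specificity).
#' @slot minSpecificity the configured specificity floor.
#' @export
setClass("CutoffResult",
  representation(threshold = "numeric", sensitivity = "numeric",
                 specificity = "numeric", roc = "data.frame",
                 minSpecificity = "numeric")
)

setValidity("CutoffResult", function(object) {
  if (object@specificity < object@minSpecificity - 1e-12)
    return("achieved specificity must be >= the configured minimum")
  TRUE
})

#' Tumor-informed ctDNA call for one sample
#'
#' @slot patientId,timepoint character(1).
#' @slot variants data.frame of surviving variant calls.
#' @slot status `"positive"` iff at least one variant survived the filter
#'   cascade (and background test, when applied), else `"negative"`.
#' @slot maxVAF numeric(1), max VAF over surviving calls; 0 if none.
#' @export
setClass("CtdnaResult",
  representation(patientId = "character", timepoint = "character",
                 variants = "data.frame", status = "character",
                 maxVAF = "numeric")
)

setValidity("CtdnaResult", function(object) {
  pos <- nrow(object@variants) > 0L
  if (object@status != ifelse(pos, "positive", "negative"))
    return("status must be positive iff surviving variants exist")
  if (pos && abs(object@maxVAF - max(object@variants$vaf)) > 1e-12)
    return("maxVAF must equal the maximum surviving VAF")
  if (!pos && object@maxVAF != 0) return("maxVAF must be 0 when negative")
  TRUE
})

#' Confusion-matrix summary with exact confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP) and NPV
#' TN/(TN+FN), each on the percent scale with an exact Clopper–Pearson 95% CI.
#'
#' @slot counts named numeric: TP, FP, TN, FN.
#' @slot metrics data.frame with columns `metric`, `estimate`, `lower`,
#'   `upper` (percent scale, full precision; display rounds to one decimal).
#' @export
setClass("ConfusionSummary",
  representation(counts = "numeric", metrics = "data.frame")
)

#' One synthetic patient sample
#'
#' @slot patientId character(1).
#' @slot theta numeric(1) tumor fraction in \[0,1\].
#' @slot timepoint `"landmark"` or `"longitudinal"`.
#' @slot fragments a [FragmentSet].
#' @slot outcome data.frame row: `time_days`, `event`, plus clinical
#'   covariates.
#' @slot variants data.frame variant table (possibly empty until simulated).
#' @export
setClass("SyntheticPatient",
  representation(patientId = "character", theta = "numeric",
                 timepoint = "character", fragments = "FragmentSet",
                 outcome = "data.frame", variants = "data.frame")
)

setValidity("SyntheticPatient", function(object) {
  if (object@theta < 0 || object@theta > 1) return("theta must lie in [0,1]")
  if (length(object@fragments@fragments) == 0L)
    return("fragment count must be positive")
  if (nrow(object@outcome) && any(object@outcome$time_days <= 0))
    return("outcome time must be positive")
  TRUE
})
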