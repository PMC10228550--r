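#' Accessors for fragMRD classes
#'
#' Small accessor family: `sampleId()`, `timepoint()`, `provenance()` for
#' [FragmentSet]; `binRanges()`, `gcContent()`, `binIds()` for [BinSet] and
#' profiles; `featureValues()`/`featureMatrix()` for feature containers;
#' `riskScores()`, `threshold()`, `ctdnaStatusOf()`, `maxVAF()`,
#' `confusionCounts()`, `metricsTable()`, `tumorFraction()` for results.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot content (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("sampleId", "FragmentSet", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "FSRProfile", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("timepoint", "FragmentSet", function(x) x@timepoint)
#' @rdname accessors
#' @export
setMethod("provenance", "FragmentSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("granges", "FragmentSet", function(x, ...) x@fragments)

#' @rdname accessors
#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

#' @rdname accessors
#' @export
setMethod("binRanges", "BinSet", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("binRanges", "ToyGenome", function(x) x@gcBins)
#' @rdname accessors
#' @export
setMethod("gcContent", "BinSet", function(x) x@bins$gc)
#' @rdname accessors
#' @export
setMethod("gcContent", "ToyGenome", function(x) x@gcBins$gc)
#' @rdname accessors
#' @export
setMethod("binIds", "BinSet", function(x) binIdOf(x@bins))
#' @rdname accessors
#' @export
setMethod("binIds", "FSRProfile", function(x) x@binIds)
#' @rdname accessors
#' @export
setMethod("binIds", "BinCounts", function(x) x@binIds)

#' @rdname accessors
#' @export
setMethod("featureValues", "FSRProfile", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FSRMatrix", function(x) x@x)

#' @rdname accessors
#' @export
setMethod("riskScores", "RiskScoreSet", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("threshold", "CutoffResult", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("coef", "CoxnetFit", function(object, ...) object@coefficients)

#' @rdname accessors
#' @export
setMethod("ctdnaStatusOf", "CtdnaResult", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("maxVAF", "CtdnaResult", function(x) x@maxVAF)

#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionSummary", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("metricsTable", "ConfusionSummary", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("tumorFraction", "SyntheticPatient", function(x) x@theta)
#' @rdname accessors
#' @export
setMethod("sampleId", "SyntheticPatient", function(x) x@patientId)
#' @rdname accessors
#' @export
setMethod("timepoint", "SyntheticPatient", function(x) x@timepoint)

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet '%s' (%s): %d fragments\n", object@sampleId,
              object@timepoint, length(object@fragments)))
  ds <- object@provenance$downsamplingFactor
  if (!is.null(ds)) cat(sprintf("  downsampling factor: %.4f\n", ds))
})

setMethod("show", "BinSet", function(object) {
  cat(sprintf("BinSet: %d bins of %g bp (%d unmasked)\n", length(object@bins),
              object@binSize, sum(!object@bins$masked)))
})

setMethod("show", "FSRProfile", function(object) {
  cat(sprintf("FSRProfile '%s': %d features over %d bins (GC-corrected: %s)\n",
              object@sampleId, length(object@features),
              length(object@binIds), object@gcCorrected))
})

setMethod("show", "FSRMatrix", function(object) {
  cat(sprintf("FSRMatrix: %d samples x %d features (standardized: %s)\n",
              nrow(object@x), ncol(object@x), length(object@center) > 0))
})

setMethod("show", "CoxnetFit", function(object) {
  nz <- sum(object@coefficients != 0)
  cat(sprintf("CoxnetFit: %d/%d nonzero coefficients, l1Ratio=%.2f, lambda=%.4g\n",
              nz, length(object@coefficients), object@l1Ratio, object@penalty))
})

setMethod("show", "RiskScoreSet", function(object) {
  cat(sprintf("RiskScoreSet: %d leave-one-out risk scores (%d flagged)\n",
              nrow(object@scores), sum(object@scores$flagged)))
})

setMethod("show", "CutoffResult", function(object) {
  cat(sprintf(
    "CutoffResult: threshold %.4g -> sensitivity %.1f%% at specificity %.1f%% (floor %.0f%%)\n",
    object@threshold, 100 * object@sensitivity, 100 * object@specificity,
    100 * object@minSpecificity))
})

setMethod("show", "CtdnaResult", function(object) {
  cat(sprintf("CtdnaResult %s/%s: %s (%d surviving variants, max VAF %.4f)\n",
              object@patientId, object@timepoint, object@status,
              nrow(object@variants), object@maxVAF))
})

setMethod("show", "ConfusionSummary", function(object) {
  cts <- object@counts
  cat(sprintf("ConfusionSummary: TP=%d FP=%d TN=%d FN=%d\n",
              cts["TP"], cts["FP"], cts["TN"], cts["FN"]))
  m <- object@metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s undefined\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %.1f%% (95%% CI: %.1f-%.1f)\n", m$metric[i],
                  m$estimate[i], m$lower[i], m$upper[i]))
    }
  }
})

setMethod("show", "SyntheticPatient", function(object) {
  cat(sprintf("SyntheticPatient %s (%s): theta=%.3f, %d fragments, event=%s\n",
              object@patientId, object@timepoint, object@theta,
              length(object@fragments@fragments),
              if (nrow(object@outcome)) object@outcome$event else NA))
})
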