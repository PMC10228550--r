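#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname accessors
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname accessors
#' @export
setGeneric("binIds", function(x) standardGeneric("binIds"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))

#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setGeneric("ctdnaStatusOf", function(x) standardGeneric("ctdnaStatusOf"))

#' @rdname accessors
#' @export
setGeneric("maxVAF", function(x) standardGeneric("maxVAF"))

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname accessors
#' @export
setGeneric("tumorFraction", function(x) standardGeneric("tumorFraction"))
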