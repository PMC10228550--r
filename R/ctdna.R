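#' Tumor-informed plasma variant filter cascade
#'
#' A plasma call survives iff it (i) belongs to the paired tumor-tissue
#' mutational profile, (ii) is not on the clonal hematopoiesis (CHIP)
#' blacklist, and (iii) has zero supporting reads in the paired leukocyte
#' control. The three predicates are independent, so the cascade is
#' order-invariant; removals are tallied per reason.
#'
#' @param plasma data.frame of plasma calls with columns `chrom`, `pos`,
#'   `ref`, `alt`, `alt_reads`, `depth`, `vaf`, `leukocyte_alt_reads`.
#' @param tissueProfile character keys `"chrom:pos:ref:alt"` of tissue
#'   variants (or a data.frame with those columns).
#' @param blacklist character keys (or data.frame) of CHIP variants.
#' @return List with `surviving` (data.frame) and `removed`, a named tally
#'   over reasons `notInTissue`, `blacklist`, `leukocyteSupport` (a call
#'   failing several predicates is tallied under each).
#' @export
filterVariants <- function(plasma, tissueProfile, blacklist = character()) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(plasma)))
    stop("plasma table must carry chrom, pos, ref, alt", call. = FALSE)
  bad <- which(is.na(plasma$chrom) | is.na(plasma$pos) |
                 is.na(plasma$ref) | is.na(plasma$alt))
  if (length(bad))
    stop("malformed variant key in plasma row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.data.frame(tissueProfile)) tissueProfile <- variantKey(tissueProfile)
  if (is.data.frame(blacklist)) blacklist <- variantKey(blacklist)
  key <- variantKey(plasma)
  inTissue <- key %in% tissueProfile
  onBlacklist <- key %in% blacklist
  leuko <- plasma$leukocyte_alt_reads
  if (is.null(leuko)) leuko <- rep(0L, nrow(plasma))
  hasLeuko <- leuko >= 1L
  keep <- inTissue & !onBlacklist & !hasLeuko
  list(surviving = plasma[keep, , drop = FALSE],
       removed = c(notInTissue = sum(!inTissue),
                   blacklist = sum(onBlacklist),
                   leukocyteSupport = sum(hasLeuko)))
}

#' Normal-pool background noise test for a plasma variant
#'
#' One-sided exact binomial test of the observed alt reads against the
#' normal-pool background error rate: p = P(X >= alt) for
#' X ~ Binomial(depth, rate). The call is kept when p < alpha. A background
#' rate of zero is replaced by the smallest positive double, so any alt
#' support at all is significant; zero depth drops the call with a warning.
#'
#' @param alt,depth alt read count(s) and total depth(s); vectorized.
#' @param rate per-site background alt-read rate(s) from the normal pool
#'   (recycled; use a single global rate as fallback).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `p` and `keep`.
#' @export
backgroundTest <- function(alt, depth, rate, alpha = 0.05) {
  checkScalar(alpha, "alpha", min = 0, max = 1)
  n <- max(length(alt), length(depth), length(rate))
  alt <- rep_len(alt, n); depth <- rep_len(depth, n); rate <- rep_len(rate, n)
  if (any(rate < 0 | rate >= 1))
    stop("background rates must lie in [0, 1)", call. = FALSE)
  rate[rate == 0] <- .Machine$double.xmin
  p <- ifelse(alt <= 0, 1,
              stats::pbinom(alt - 1, pmax(depth, 1), rate, lower.tail = FALSE))
  keep <- p < alpha & depth > 0
  if (any(depth == 0)) {
    warning("zero-depth call(s) dropped")
    p[depth == 0] <- NA_real_
  }
  data.frame(p = p, keep = keep)
}

#' ctDNA MRD status from surviving variant calls
#'
#' @param surviving data.frame of calls surviving [filterVariants()] (and,
#'   when applied, [backgroundTest()]) for one patient sample; may be empty.
#' @param patientId,timepoint labels (inferred from the table when present).
#' @return A [CtdnaResult]: positive iff at least one call survived, with
#'   the max VAF over surviving calls (0 if none).
#' @export
ctdnaStatus <- function(surviving, patientId = NULL, timepoint = "landmark") {
  if (is.null(patientId))
    patientId <- if (nrow(surviving) && "patient_id" %in% names(surviving))
      surviving$patient_id[1] else "sample"
  if (nrow(surviving) && length(unique(surviving$patient_id %||% patientId)) > 1L)
    stop("all calls must share one patient", call. = FALSE)
  pos <- nrow(surviving) > 0L
  new("CtdnaResult", patientId = patientId, timepoint = timepoint,
      variants = as.data.frame(surviving),
      status = if (pos) "positive" else "negative",
      maxVAF = if (pos) max(surviving$vaf) else 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full tumor-informed ctDNA call for one sample
#'
#' Applies the filter cascade and then, when a normal pool is supplied, the
#' background test to the survivors.
#'
#' @param plasma plasma variant table (see [filterVariants()]).
#' @param tissueProfile,blacklist variant key sets.
#' @param poolRate per-site or global background rate(s); `NULL` skips the
#'   background test.
#' @param alpha significance level for the background test.
#' @param patientId,timepoint labels for the result.
#' @return A [CtdnaResult].
#' @export
callCtdna <- function(plasma, tissueProfile, blacklist = character(),
                      poolRate = NULL, alpha = 0.05, patientId = NULL,
                      timepoint = "landmark") {
  surv <- filterVariants(plasma, tissueProfile, blacklist)$surviving
  if (!is.null(poolRate) && nrow(surv)) {
    bt <- backgroundTest(surv$alt_reads, surv$depth, poolRate, alpha)
    surv <- surv[which(bt$keep), , drop = FALSE]
  }
  ctdnaStatus(surv, patientId = patientId, timepoint = timepoint)
}
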