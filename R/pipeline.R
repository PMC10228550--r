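#' Default run configuration
#'
#' Every tunable of the pipeline in one serializable list: synthetic cohort
#' settings, size-class scheme bounds, bin size, mask threshold, GC smoother
#' flexibility, Coxnet hyperparameters, the specificity floor for the MRD
#' cutoff, the ctDNA background-test level, and the seed. The configuration
#' is written verbatim into each run's output directory.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return Named list of configuration values.
#' @export
runConfig <- function(...) {
  cfg <- list(
    nPatients = 20, recurrenceFraction = 0.3,
    thetaHigh = 0.05, thetaLow = 0, hazardCoefficient = 100,
    fragmentsPerSample = 2e4,
    nChrom = 4, chromLen = 3e7, binSize = 5e6, maskFraction = 0,
    maskThreshold = 0.5, gcBiasCoef = 2,
    timepoint = "landmark",
    targetCoverage = 5, smootherDf = 6,
    l1Ratio = 0.5, nlambda = 100, innerFolds = 5,
    minSpecificity = 0.9, alpha = 0.05, poolRate = 1e-4,
    nTrue = 10, nChip = 3, nLeuko = 3, variantDepth = 1000,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

stageLog <- function(logPath, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "", file = logPath, append = TRUE)
  invisible(msg)
}

#' Run the MRD pipeline end to end
#'
#' Orchestrates the stages `simulate` (synthetic cohort), `extract`
#' (bins + FSR features), `fit` (leave-one-out Coxnet risk scores and
#' specificity-constrained cutoff), `ctdna` (tumor-informed variant calls)
#' and `evaluate` (confusion metrics, AUC, combined calls). Each stage
#' writes its outputs and per-stage record counts into `outDir`, along with
#' a verbatim config snapshot, so a run is reproducible from the directory
#' alone; re-running with an identical config and seed reproduces identical
#' outputs.
#'
#' @param config list from [runConfig()].
#' @param stages subset of
#'   `c("simulate", "extract", "fit", "ctdna", "evaluate")`.
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly. Side files: `config.json`, `log.txt`,
#'   `clinical.tsv`, `features.tsv`, `scores.tsv`, `model.json`,
#'   `ctdna.tsv`, `evaluation.json` (per requested stages).
#' @export
runPipeline <- function(config = runConfig(),
                        stages = c("simulate", "extract", "fit", "ctdna",
                                   "evaluate"),
                        outDir = tempfile("fragmrd_run_")) {
  stages <- match.arg(stages, c("simulate", "extract", "fit", "ctdna",
                                "evaluate"), several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  cat("", file = logPath)
  jsonlite::write_json(config, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  need <- function(stage, file) {
    p <- file.path(outDir, file)
    if (!file.exists(p))
      stop(sprintf("stage '%s' requires missing input '%s'", stage, file),
           call. = FALSE)
    p
  }

  cohort <- NULL; genome <- NULL; bins <- NULL; fm <- NULL

  if ("simulate" %in% stages) {
    genome <- buildToyGenome(config$nChrom, config$chromLen, config$binSize,
                             config$maskFraction, seed = config$seed)
    cohort <- simulateCohort(config$nPatients, config$recurrenceFraction,
                             config$thetaHigh, config$thetaLow,
                             config$hazardCoefficient,
                             config$fragmentsPerSample, genome,
                             seed = config$seed,
                             timepoints = config$timepoint,
                             gcBiasCoef = config$gcBiasCoef)
    clin <- clinicalTable(cohort)
    utils::write.table(clin, file.path(outDir, "clinical.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stageLog(logPath, "simulate: %d patient samples, %d fragments each",
             length(cohort), config$fragmentsPerSample)
  }

  if ("extract" %in% stages) {
    if (is.null(cohort))
      stop("stage 'extract' requires missing input 'simulated cohort' ",
           "(run the simulate stage first)", call. = FALSE)
    bins <- makeBins(genome, config$binSize, config$maskThreshold)
    gsize <- genomeSize(genome)
    profiles <- lapply(cohort, function(p) {
      fs <- downsampleToCoverage(p@fragments, config$targetCoverage, gsize,
                                 seed = config$seed)
      fsrProfile(fs, bins, correctGC = TRUE, df = config$smootherDf)
    })
    fm <- assembleMatrix(profiles)
    writeFeatureMatrix(fm, file.path(outDir, "features.tsv"))
    stageLog(logPath, "extract: %d x %d feature matrix over %d unmasked bins",
             nrow(fm@x), ncol(fm@x), sum(!bins@bins$masked))
  }

  if ("fit" %in% stages) {
    if (is.null(fm)) fm <- readFeatureMatrix(need("fit", "features.tsv"))
    clin <- utils::read.delim(need("fit", "clinical.tsv"))
    clin <- clin[match(rownames(fm@x), clin$patient_id), ]
    rs <- loocvRiskScores(fm, clin, l1Ratio = config$l1Ratio,
                          nlambda = config$nlambda,
                          innerFolds = config$innerFolds, seed = config$seed,
                          timepoint = config$timepoint)
    cut <- selectCutoff(rs, clin$event, config$minSpecificity)
    cls <- classifyRisk(rs, cut)
    out <- cbind(rs@scores, risk_class = as.character(cls))
    utils::write.table(out, file.path(outDir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(threshold = cut@threshold,
                              sensitivity = cut@sensitivity,
                              specificity = cut@specificity,
                              minSpecificity = cut@minSpecificity,
                              seed = config$seed),
                         file.path(outDir, "model.json"), auto_unbox = TRUE,
                         digits = NA)
    stageLog(logPath,
             "fit: %d LOOCV scores, cutoff %.4g (sens %.3f at spec %.3f)",
             nrow(out), cut@threshold, cut@sensitivity, cut@specificity)
  }

  if ("ctdna" %in% stages) {
    if (is.null(cohort))
      stop("stage 'ctdna' requires missing input 'simulated cohort' ",
           "(run the simulate stage first)", call. = FALSE)
    rows <- lapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]
      vt <- simulateVariantTable(p, config$nTrue, config$nChip, config$nLeuko,
                                 config$variantDepth,
                                 seed = childSeed(config$seed, i))
      res <- callCtdna(vt, tissueProfile = vt[vt$in_tissue, ],
                       blacklist = vt[vt$in_blacklist, ],
                       poolRate = config$poolRate, alpha = config$alpha,
                       patientId = p@patientId, timepoint = p@timepoint)
      data.frame(patient_id = p@patientId, timepoint = p@timepoint,
                 status = res@status, max_vaf = res@maxVAF,
                 n_surviving = nrow(res@variants))
    })
    ct <- do.call(rbind, rows)
    utils::write.table(ct, file.path(outDir, "ctdna.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stageLog(logPath, "ctdna: %d samples, %d positive", nrow(ct),
             sum(ct$status == "positive"))
  }

  if ("evaluate" %in% stages) {
    scores <- utils::read.delim(need("evaluate", "scores.tsv"))
    clin <- utils::read.delim(need("evaluate", "clinical.tsv"))
    clin <- clin[match(scores$sample, clin$patient_id), ]
    fragCM <- confusionMetrics(scores$risk_class, clin$event)
    auc <- rocAuc(scores$score, clin$event)
    report <- list(
      fragmentomics = list(counts = as.list(fragCM@counts),
                           metrics = fragCM@metrics),
      auc = auc
    )
    ctPath <- file.path(outDir, "ctdna.tsv")
    if (file.exists(ctPath)) {
      ct <- utils::read.delim(ctPath)
      ct <- ct[match(scores$sample, ct$patient_id), ]
      ctCM <- confusionMetrics(ct$status == "positive", clin$event)
      comb <- combineCalls(scores$risk_class, ct$status)
      combCM <- confusionMetrics(comb$combined, clin$event)
      report$ctdna <- list(counts = as.list(ctCM@counts), metrics = ctCM@metrics)
      report$combined <- list(counts = as.list(combCM@counts),
                              metrics = combCM@metrics)
    }
    jsonlite::write_json(report, file.path(outDir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    stageLog(logPath, "evaluate: AUC %.3f", auc$auc)
  }

  invisible(outDir)
}
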