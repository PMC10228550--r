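#' Exact (Clopper–Pearson) binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles, reported on the percent
#' scale at full precision (display conventionally rounds to one decimal).
#' The lower bound is 0 when `k = 0` and the upper bound is 100 when
#' `k = n`.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` in percent.
#' @examples
#' exactBinomCI(10, 23)  # 23.19 to 65.51
#' @export
exactBinomCI <- function(k, n, conf = 0.95) {
  checkScalar(n, "n", min = 1, integer = TRUE)
  checkScalar(k, "k", min = 0, max = n, integer = TRUE)
  checkScalar(conf, "conf", min = 0, max = 1)
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Confusion-matrix metrics with exact confidence intervals
#'
#' Computes TP/FP/TN/FN and sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' PPV TP/(TP+FP), NPV TN/(TN+FN), each on the percent scale with an exact
#' Clopper–Pearson CI. A metric whose denominator is empty (e.g. PPV with no
#' positive calls) is reported as `NA` rather than fabricated.
#'
#' @param predicted binary calls (logical, 0/1, or factor with `"high"`
#'   meaning positive).
#' @param truth binary recurrence labels, same conventions; both classes
#'   must be represented.
#' @param conf confidence level (default 0.95).
#' @return A [ConfusionSummary].
#' @export
confusionMetrics <- function(predicted, truth, conf = 0.95) {
  toBin <- function(v) {
    if (is.factor(v) || is.character(v))
      as.integer(as.character(v) %in% c("high", "positive", "1", "TRUE"))
    else as.integer(as.logical(v))
  }
  p <- toBin(predicted); t <- toBin(truth)
  if (length(p) != length(t) || !length(p))
    stop("predicted and truth must be equal-length and non-empty", call. = FALSE)
  if (length(unique(t)) < 2L)
    warning("only one class present in truth; some metrics are undefined")
  cts <- c(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
           TN = sum(p == 0 & t == 0), FN = sum(p == 0 & t == 1))
  one <- function(name, k, n) {
    if (n == 0) return(data.frame(metric = name, estimate = NA_real_,
                                  lower = NA_real_, upper = NA_real_))
    ci <- exactBinomCI(k, n, conf)
    data.frame(metric = name, estimate = 100 * k / n, lower = ci["lower"],
               upper = ci["upper"])
  }
  m <- rbind(one("sensitivity", cts["TP"], cts["TP"] + cts["FN"]),
             one("specificity", cts["TN"], cts["TN"] + cts["FP"]),
             one("ppv", cts["TP"], cts["TP"] + cts["FP"]),
             one("npv", cts["TN"], cts["TN"] + cts["FN"]))
  rownames(m) <- NULL
  new("ConfusionSummary", counts = cts, metrics = m)
}

#' Combine fragmentomics and ctDNA calls
#'
#' A patient sample is combined-high iff the fragmentomics model called it
#' high risk OR its ctDNA status is positive; combined-low requires both a
#' low-risk fragmentomics call and a negative ctDNA status. With
#' `pool = TRUE` calls are additionally pooled across timepoints per patient
#' (high at either timepoint makes the patient high overall).
#'
#' @param frag factor/character of fragmentomics risk classes
#'   (`"high"`/`"low"`).
#' @param ctdna factor/character of ctDNA statuses
#'   (`"positive"`/`"negative"`).
#' @param patientId optional patient keys, required for `pool = TRUE`.
#' @param pool pool calls across timepoints per patient.
#' @return data.frame with columns `patient` (when given), `frag`, `ctdna`,
#'   `combined`; pooled mode returns one row per patient.
#' @export
combineCalls <- function(frag, ctdna, patientId = NULL, pool = FALSE) {
  fragHigh <- as.character(frag) == "high"
  ctdnaPos <- as.character(ctdna) == "positive"
  if (length(fragHigh) != length(ctdnaPos))
    stop("frag and ctdna must be aligned", call. = FALSE)
  comb <- fragHigh | ctdnaPos
  df <- data.frame(frag = ifelse(fragHigh, "high", "low"),
                   ctdna = ifelse(ctdnaPos, "positive", "negative"),
                   combined = factor(ifelse(comb, "high", "low"),
                                     levels = c("low", "high")),
                   stringsAsFactors = FALSE)
  if (!is.null(patientId)) df <- cbind(patient = patientId, df)
  if (pool) {
    if (is.null(patientId)) stop("pooling requires patientId", call. = FALSE)
    agg <- tapply(df$combined == "high", df$patient, any)
    df <- data.frame(patient = names(agg),
                     combined = factor(ifelse(agg, "high", "low"),
                                       levels = c("low", "high")),
                     stringsAsFactors = FALSE)
  }
  df
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC as the normalized Mann–Whitney U statistic (ties count 0.5), with the
#' DeLong variance-based confidence interval, computed via \pkg{pROC} with a
#' fixed direction (higher score = positive class) so null data stay at 0.5.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (0/1 or logical); both classes required.
#' @param conf confidence level (default 0.95).
#' @return List with `auc`, `lower`, `upper`.
#' @export
rocAuc <- function(scores, labels, conf = 0.95) {
  lab <- as.integer(as.logical(labels))
  if (length(unique(lab)) < 2L)
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = lab, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), lower = ci[1], upper = ci[3])
}

#' Cox proportional-hazards summary (univariate or covariate-adjusted)
#'
#' Fits a Cox model (Breslow ties) of the outcome on a grouping variable,
#' optionally adjusted for a covariate table (the usual clinical set: age,
#' sex, smoking, adjuvant therapy, stage, histology). Also reports the
#' log-rank test p-value for the unadjusted grouping.
#'
#' @param group binary or categorical grouping (first level = reference).
#' @param outcomes data.frame with `time_days`, `event`.
#' @param covariates optional data.frame of covariates, row-aligned.
#' @param conf confidence level.
#' @return data.frame with one row per non-reference coefficient of `group`:
#'   `term`, `hr`, `lower`, `upper`, `p`, plus attribute `"logrank_p"` for
#'   the unadjusted group comparison.
#' @export
coxHR <- function(group, outcomes, covariates = NULL, conf = 0.95) {
  y <- makeSurv(outcomes)
  g <- factor(group)
  perLevel <- tapply(y[, "status"], g, sum)
  if (any(is.na(perLevel)) || any(perLevel < 1))
    warning("a group level has no events; its estimate is unstable")
  dat <- data.frame(group = g)
  form <- y ~ group
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cov <- as.data.frame(covariates)
    dat <- cbind(dat, cov)
    form <- stats::as.formula(paste("y ~ group +",
                                    paste(names(cov), collapse = " + ")))
  }
  fit <- coxph(form, data = dat, ties = "breslow")
  s <- summary(fit, conf.int = conf)
  idx <- grep("^group", rownames(s$coefficients))
  out <- data.frame(term = rownames(s$coefficients)[idx],
                    hr = s$coefficients[idx, "exp(coef)"],
                    lower = s$conf.int[idx, 3],
                    upper = s$conf.int[idx, 4],
                    p = s$coefficients[idx, "Pr(>|z|)"],
                    row.names = NULL)
  if (nlevels(g) > 1L) {
    sd <- survdiff(y ~ g)
    attr(out, "logrank_p") <- stats::pchisq(sd$chisq, df = nlevels(g) - 1,
                                            lower.tail = FALSE)
  }
  out
}

#' Lead time of a molecular MRD call over radiographic recurrence
#'
#' @param callDay day post-surgery of the positive MRD call.
#' @param recurrenceDay day post-surgery of radiographic recurrence.
#' @return Numeric vector `recurrenceDay - callDay`; negative values mean
#'   the call came after recurrence.
#' @export
leadTime <- function(callDay, recurrenceDay) {
  as.numeric(recurrenceDay) - as.numeric(callDay)
}

#' Cohort lead-time summary
#'
#' Negative leads (recurrence before the call) are flagged and excluded from
#' the summary, which reports the median and range over valid leads.
#'
#' @param callDay,recurrenceDay vectors of days post-surgery.
#' @return List with `leads` (all values), `excluded` (count of negative
#'   leads), `median`, `min`, `max` over the valid leads.
#' @export
leadTimeSummary <- function(callDay, recurrenceDay) {
  lt <- leadTime(callDay, recurrenceDay)
  valid <- lt[lt >= 0]
  list(leads = lt, excluded = sum(lt < 0),
       median = if (length(valid)) stats::median(valid) else NA_real_,
       min = if (length(valid)) min(valid) else NA_real_,
       max = if (length(valid)) max(valid) else NA_real_)
}
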