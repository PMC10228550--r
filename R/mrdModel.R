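#' @importFrom survival Surv coxph survdiff
#' @importFrom glmnet glmnet cv.glmnet
NULL

makeSurv <- function(outcomes) {
  if (is(outcomes, "Surv")) return(outcomes)
  if (!all(c("time_days", "event") %in% names(outcomes)))
    stop("outcomes must carry 'time_days' and 'event' columns", call. = FALSE)
  if (any(outcomes$time_days <= 0)) stop("event times must be positive", call. = FALSE)
  if (!all(outcomes$event %in% c(0, 1)))
    stop("event indicator must be 0/1", call. = FALSE)
  Surv(outcomes$time_days, outcomes$event)
}

applyStandardization <- function(x, center, scale) {
  if (!length(center)) return(x)
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Fit an elastic-net penalized Cox model on FSR features
#'
#' Maximizes the elastic-net penalized Cox partial likelihood (Breslow tie
#' handling) on z-score standardized features. With `penalty = "auto"` the
#' penalty strength is chosen along a computed path by inner 5-fold
#' cross-validated partial-likelihood deviance on the training samples only
#' (fold assignment seeded for reproducibility).
#'
#' @param X an [FSRMatrix] or numeric matrix (samples x features).
#' @param outcomes data.frame with `time_days` and `event`, or a
#'   [survival::Surv] object, row-aligned with `X`.
#' @param l1Ratio elastic-net mixing parameter in \[0,1\] (default 0.5).
#' @param penalty `"auto"` (inner-CV selection) or a fixed non-negative
#'   numeric penalty strength.
#' @param nlambda length of the computed penalty path (default 100).
#' @param innerFolds inner cross-validation folds (default 5).
#' @param seed seed governing the inner fold assignment.
#' @param standardize fit and store per-feature center/scale on the training
#'   data (default TRUE).
#' @return A [CoxnetFit].
#' @export
fitCoxnet <- function(X, outcomes, l1Ratio = 0.5, penalty = "auto",
                      nlambda = 100, innerFolds = 5, seed = 1,
                      standardize = TRUE) {
  x <- if (is(X, "FSRMatrix")) X@x else as.matrix(X)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- makeSurv(outcomes)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (sum(y[, "status"]) < 1) stop("no events in training data", call. = FALSE)
  checkScalar(l1Ratio, "l1Ratio", min = 0, max = 1)
  center <- numeric(0); scale <- numeric(0)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd); scale[scale == 0] <- 1
    x <- applyStandardization(x, center, scale)
  }
  if (identical(penalty, "auto")) {
    lam <- withSeed(seed, {
      foldid <- sample(rep(seq_len(innerFolds), length.out = n))
      cv <- cv.glmnet(x, y, family = "cox", alpha = l1Ratio, foldid = foldid,
                      nlambda = nlambda, standardize = FALSE)
      cv$lambda.min
    })
  } else {
    checkScalar(penalty, "penalty", min = 0)
    lam <- penalty
  }
  fit <- glmnet(x, y, family = "cox", alpha = l1Ratio, lambda = lam,
                standardize = FALSE, thresh = 1e-10)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(x)
  new("CoxnetFit", coefficients = beta, l1Ratio = l1Ratio, penalty = lam,
      center = center, scale = scale)
}

#' Risk scores (linear predictor) of a fitted Coxnet model
#'
#' @param fit a [CoxnetFit].
#' @param X an [FSRMatrix] or numeric matrix; the fit's stored
#'   standardization is applied before scoring.
#' @return Numeric vector of linear-predictor risk scores.
#' @export
predictRisk <- function(fit, X) {
  x <- if (is(X, "FSRMatrix")) X@x else as.matrix(X)
  x <- applyStandardization(x, fit@center, fit@scale)
  as.numeric(x %*% fit@coefficients)
}

#' Leave-one-out cross-validated MRD risk scores
#'
#' For each sample i the remaining n-1 samples are standardized and used to
#' fit a penalized Cox model (penalty chosen by inner 5-fold CV on those
#' training samples only); sample i is then scored with the fitted linear
#' predictor. The loop runs until every sample has a score, so no score ever
#' depends on the sample's own outcome. A training fold without events is
#' fitted as the null model (score 0) and flagged.
#'
#' @param X an [FSRMatrix] or numeric matrix (samples x features).
#' @param outcomes outcome table aligned with `X` (see [fitCoxnet()]).
#' @param l1Ratio,nlambda,innerFolds passed to [fitCoxnet()].
#' @param seed base seed; each fold's inner-CV assignment derives from it.
#' @param timepoint label recorded with the scores.
#' @return A [RiskScoreSet].
#' @export
loocvRiskScores <- function(X, outcomes, l1Ratio = 0.5, nlambda = 100,
                            innerFolds = 5, seed = 1, timepoint = "landmark") {
  x <- if (is(X, "FSRMatrix")) X@x else as.matrix(X)
  n <- nrow(x)
  if (n < 3L) stop("leave-one-out cross-validation needs n >= 3", call. = FALSE)
  y <- makeSurv(outcomes)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  score <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    yi <- y[-i, , drop = FALSE]
    if (sum(yi[, "status"]) < 1) {
      score[i] <- 0; flagged[i] <- TRUE
      next
    }
    fit <- tryCatch(
      fitCoxnet(x[-i, , drop = FALSE], yi, l1Ratio = l1Ratio,
                penalty = "auto", nlambda = nlambda,
                innerFolds = innerFolds, seed = childSeed(seed, i)),
      error = function(e) NULL)  # degenerate fold (e.g. a lone event)
    if (is.null(fit)) {
      score[i] <- 0; flagged[i] <- TRUE
      next
    }
    score[i] <- predictRisk(fit, x[i, , drop = FALSE])
  }
  new("RiskScoreSet",
      scores = data.frame(sample = ids, score = score, fold = seq_len(n),
                          timepoint = timepoint, flagged = flagged,
                          stringsAsFactors = FALSE))
}

#' Select the specificity-constrained MRD cutoff
#'
#' Sweeps all achievable thresholds on the score set (midpoints between
#' consecutive distinct scores, plus sentinels below and above the range) and
#' among those with specificity at or above `minSpecificity` picks the one
#' with maximal sensitivity; ties are broken by higher specificity, then by
#' higher threshold. A sample is called high risk iff its score is strictly
#' above the threshold, so specificity 1 is always attainable and the
#' constraint can always be met.
#'
#' @param scores a [RiskScoreSet] or numeric vector.
#' @param labels binary recurrence labels (0/1 or logical) aligned with the
#'   scores.
#' @param minSpecificity specificity floor (default 0.90).
#' @return A [CutoffResult] with the ROC points of the sweep.
#' @export
selectCutoff <- function(scores, labels, minSpecificity = 0.9) {
  s <- if (is(scores, "RiskScoreSet")) scores@scores$score else as.numeric(scores)
  lab <- as.integer(labels)
  if (length(s) != length(lab)) stop("scores and labels must align", call. = FALSE)
  if (!all(lab %in% c(0, 1)) || length(unique(lab)) < 2L)
    stop("both classes must be present", call. = FALSE)
  checkScalar(minSpecificity, "minSpecificity", min = 0, max = 1)
  u <- sort(unique(s))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)])
  nPos <- sum(lab == 1); nNeg <- sum(lab == 0)
  sens <- vapply(cand, function(t) sum(s > t & lab == 1) / nPos, 0)
  spec <- vapply(cand, function(t) sum(s <= t & lab == 0) / nNeg, 0)
  roc <- data.frame(threshold = cand, sensitivity = sens, specificity = spec)
  ok <- which(spec >= minSpecificity)
  ord <- ok[order(sens[ok], spec[ok], cand[ok], decreasing = TRUE)]
  best <- ord[1]
  new("CutoffResult", threshold = cand[best], sensitivity = sens[best],
      specificity = spec[best], roc = roc, minSpecificity = minSpecificity)
}

#' Classify samples as high or low MRD risk
#'
#' @param scores a [RiskScoreSet] or numeric vector.
#' @param cutoff a [CutoffResult] or a fixed numeric threshold.
#' @return Factor with levels `c("low", "high")`; high iff score strictly
#'   above the threshold.
#' @export
classifyRisk <- function(scores, cutoff) {
  s <- if (is(scores, "RiskScoreSet")) scores@scores$score else as.numeric(scores)
  t <- if (is(cutoff, "CutoffResult")) cutoff@threshold else as.numeric(cutoff)
  factor(ifelse(s > t, "high", "low"), levels = c("low", "high"))
}

#' Persist a Coxnet model artifact as JSON
#' @param fit a [CoxnetFit].
#' @param cutoff optional [CutoffResult] stored alongside.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeModelJson <- function(fit, path, cutoff = NULL) {
  obj <- list(coefficients = as.list(fit@coefficients[fit@coefficients != 0]),
              l1Ratio = fit@l1Ratio, penalty = fit@penalty,
              center = fit@center, scale = fit@scale)
  if (!is.null(cutoff))
    obj$cutoff <- list(threshold = cutoff@threshold,
                       sensitivity = cutoff@sensitivity,
                       specificity = cutoff@specificity,
                       minSpecificity = cutoff@minSpecificity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
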