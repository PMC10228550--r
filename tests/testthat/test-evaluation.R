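test_that("Clopper-Pearson intervals match the exact binomial test and nest across levels", {
  ci <- exactBinomCI(10, 23)
  bt <- 100 * stats::binom.test(10, 23)$conf.int
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-9)
  expect_equal(exactBinomCI(0, 15)[["lower"]], 0)
  expect_equal(exactBinomCI(15, 15)[["upper"]], 100)

  for (n in seq(5, 200, by = 13)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      c90 <- exactBinomCI(k, n, conf = 0.90)
      c95 <- exactBinomCI(k, n, conf = 0.95)
      expect_gte(c90[["lower"]], c95[["lower"]])
      expect_lte(c90[["upper"]], c95[["upper"]])
    }
  }
})

test_that("confusion metrics are integer-consistent and flag undefined cells", {
  pred <- c(rep(1, 16), rep(0, 71))
  truth <- c(rep(1, 10), rep(0, 6), rep(1, 13), rep(0, 58))
  cm <- confusionMetrics(pred, truth)
  cts <- confusionCounts(cm)
  m <- metricsTable(cm)
  for (i in seq_len(nrow(m))) {
    kn <- switch(m$metric[i],
                 sensitivity = c(cts["TP"], cts["TP"] + cts["FN"]),
                 specificity = c(cts["TN"], cts["TN"] + cts["FP"]),
                 ppv = c(cts["TP"], cts["TP"] + cts["FP"]),
                 npv = c(cts["TN"], cts["TN"] + cts["FN"]))
    expect_equal(unname(m$estimate[i] * kn[2] / 100), unname(kn[1]),
                 tolerance = 1e-12)
  }

  perfect <- confusionMetrics(truth, truth)
  mp <- metricsTable(perfect)
  expect_true(all(mp$estimate == 100))
  expect_true(all(mp$lower > 0))
  expect_true(all(mp$upper == 100))

  nopos <- confusionMetrics(rep(0, 10), c(rep(1, 4), rep(0, 6)))
  expect_true(is.na(metricsTable(nopos)$estimate[3]))  # PPV undefined
})

test_that("combining calls is an OR that can only add sensitivity and remove specificity", {
  expect_equal(as.character(combineCalls("high", "negative")$combined), "high")
  expect_equal(as.character(combineCalls("low", "negative")$combined), "low")
  expect_equal(as.character(combineCalls("low", "positive")$combined), "high")

  set.seed(9)
  for (i in 1:50) {
    n <- 40
    truth <- rbinom(n, 1, 0.3); truth[1:2] <- 0:1
    frag <- ifelse(rbinom(n, 1, 0.3) == 1, "high", "low")
    ct <- ifelse(rbinom(n, 1, 0.2) == 1, "positive", "negative")
    comb <- combineCalls(frag, ct)$combined
    sens <- function(p) sum(p & truth == 1) / sum(truth == 1)
    spec <- function(p) sum(!p & truth == 0) / sum(truth == 0)
    expect_gte(sens(comb == "high"), max(sens(frag == "high"),
                                         sens(ct == "positive")))
    expect_lte(spec(comb == "high"), min(spec(frag == "high"),
                                         spec(ct == "positive")))
  }

  pooled <- combineCalls(c("low", "high", "low", "low"),
                         c("negative", "negative", "negative", "positive"),
                         patientId = c("A", "A", "B", "B"), pool = TRUE)
  expect_equal(as.character(pooled$combined[match(c("A", "B"),
                                                  pooled$patient)]),
               c("high", "high"))
})

test_that("AUC equals pair counting, is 1 under separation and 0.5 under the null", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)

  set.seed(10)
  for (i in 1:20) {
    n <- sample(8:50, 1)
    s <- round(rnorm(n), 1)  # rounding forces ties
    lab <- rbinom(n, 1, 0.5); lab[1:2] <- 0:1
    expect_equal(rocAuc(s, lab)$auc, pairCountAuc(s, lab), tolerance = 1e-12)
  }

  nullAuc <- vapply(1:20, function(s) {
    set.seed(100 + s)
    rocAuc(rnorm(200), rbinom(200, 1, 0.5))$auc
  }, 0)
  expect_lt(abs(mean(nullAuc) - 0.5), 0.05)
})

test_that("Cox hazard ratios recover known effects and reduce to univariate without covariates", {
  out <- data.frame(time_days = rep(rep(c(5, 10, 20, 40), each = 2), 5),
                    event = rep(1, 40))
  g <- rep(c("a", "b"), 20)  # both groups see the identical outcome vector
  hr <- coxHR(g, out)
  expect_equal(hr$hr, 1, tolerance = 1e-8)

  lhr <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 500
    grp <- rep(0:1, each = n / 2)
    tt <- round(rexp(n, 0.01 * exp(grp))) + 1
    o <- data.frame(time_days = tt, event = rep(1, n))
    log(coxHR(factor(grp), o)$hr)
  }, 0)
  se <- sd(lhr) / sqrt(20)
  expect_lt(abs(mean(lhr) - 1), 3 * se + 0.05)

  set.seed(11)
  o2 <- data.frame(time_days = round(rexp(60, 0.01)) + 1, event = rep(1, 60))
  g2 <- factor(rep(c("x", "y"), 30))
  expect_equal(coxHR(g2, o2, covariates = NULL)$hr,
               coxHR(g2, o2, covariates = data.frame())$hr)
  expect_true(is.numeric(attr(coxHR(g2, o2), "logrank_p")))
})

test_that("lead time subtracts call day from recurrence day and summarizes positive leads", {
  expect_equal(leadTime(7, 300), 293)
  s <- leadTimeSummary(c(7, 7, 7), c(300, 152, 521))
  expect_equal(s$median, 293)
  expect_equal(c(s$min, s$max), c(145, 514))

  s2 <- leadTimeSummary(c(7, 400), c(300, 200))
  expect_equal(s2$excluded, 1)
  expect_equal(s2$median, 293)
})
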