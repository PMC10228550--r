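test_that("full shrinkage zeroes every coefficient and equalizes risk scores", {
  d <- nullCohortData(n = 40, p = 30, nEvents = 12, seed = 1)
  fit <- fitCoxnet(d$x, d$outcomes, penalty = 1e9)
  expect_true(all(coef(fit) == 0))
  expect_true(all(predictRisk(fit, d$x) == 0))
  expect_error(fitCoxnet(d$x, data.frame(time_days = d$outcomes$time_days,
                                         event = rep(0, 40))), "no events")
})

test_that("lasso recovers the sign of a noiseless linear risk driver", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60; p <- 20
    x <- matrix(rnorm(n * p), n, p)
    lp <- 1.5 * x[, 1]
    tt <- round(rexp(n, 0.01 * exp(lp))) + 1
    out <- data.frame(time_days = tt, event = rep(1, n))
    fit <- fitCoxnet(x, out, l1Ratio = 1, seed = s)
    b <- coef(fit)
    b[1] > 0 && sum(b[-1] != 0) <= 5
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("duplicated features share coefficient mass without changing the linear predictor", {
  set.seed(4)
  n <- 60
  x1 <- matrix(rnorm(n * 5), n, 5)
  lp <- x1[, 1]
  out <- data.frame(time_days = round(rexp(n, 0.01 * exp(lp))) + 1,
                    event = rep(1, n))
  xdup <- cbind(x1, x1[, 1])
  colnames(xdup) <- paste0("f", 1:6)
  fitA <- fitCoxnet(x1, out, l1Ratio = 0.3, penalty = 0.05)
  fitB <- fitCoxnet(xdup, out, l1Ratio = 0.3, penalty = 0.05)
  b <- coef(fitB)
  expect_equal(unname(b[1]), unname(b[6]), tolerance = 0.01)
  expect_equal(predictRisk(fitB, xdup), predictRisk(fitA, x1),
               tolerance = 0.1)
})

test_that("leave-one-out scoring is leakage-free and handles event-free folds", {
  d <- nullCohortData(n = 20, p = 10, nEvents = 6, seed = 2)
  rs <- loocvRiskScores(d$x, d$outcomes, seed = 5)
  sc <- riskScores(rs)
  expect_equal(nrow(sc), 20L)

  ## perturbing sample i's outcome must not change sample i's own score
  out2 <- d$outcomes
  out2$event[3] <- 1 - out2$event[3]
  out2$time_days[3] <- 55
  rs2 <- loocvRiskScores(d$x, out2, seed = 5)
  expect_equal(riskScores(rs2)$score[3], sc$score[3])

  ## a single event: the fold dropping it has no events and is flagged
  out1 <- d$outcomes
  out1$event <- c(1, rep(0, 19))
  rs1 <- loocvRiskScores(d$x, out1, seed = 5)
  expect_true(riskScores(rs1)$flagged[1])
  expect_equal(riskScores(rs1)$score[1], 0)

  expect_identical(riskScores(loocvRiskScores(d$x, d$outcomes, seed = 5)), sc)
})

test_that("cutoff selection matches the exhaustive sweep and honors the specificity floor", {
  cut <- selectCutoff(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1),
                      minSpecificity = 0.9)
  expect_gt(threshold(cut), 0.2)
  expect_lte(threshold(cut), 0.3)
  expect_equal(cut@sensitivity, 1)
  expect_equal(cut@specificity, 1)

  ## perfectly separated scores
  cutP <- selectCutoff(c(rep(0, 5), rep(1, 5)), rep(0:1, each = 5), 0.9)
  expect_equal(cutP@sensitivity, 1)
  expect_equal(cutP@specificity, 1)

  set.seed(6)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    s <- round(rnorm(n), 2)
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) lab[1:2] <- 0:1
    minSpec <- sample(c(0.7, 0.8, 0.9), 1)
    got <- selectCutoff(s, lab, minSpec)
    want <- bruteForceCutoff(s, lab, minSpec)
    expect_equal(got@sensitivity, want$sens)
    expect_equal(got@specificity, want$spec)
    expect_equal(threshold(got), want$t)
    expect_gte(got@specificity, minSpec)
  }
})

test_that("raising the specificity floor never raises the selected sensitivity", {
  set.seed(7)
  s <- rnorm(60)
  lab <- rbinom(60, 1, 0.3)
  lab[1:2] <- 0:1
  floors <- seq(0.5, 1, by = 0.05)
  sens <- vapply(floors, function(ms) selectCutoff(s, lab, ms)@sensitivity, 0)
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("risk classification is a strict threshold rule", {
  cut <- selectCutoff(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1), 0.9)
  expect_equal(as.character(classifyRisk(c(0.15, 0.35), cut)),
               c("low", "high"))
  expect_true(all(classifyRisk(rnorm(20), -Inf) == "high"))
  expect_true(all(classifyRisk(rnorm(20), Inf) == "low"))
  engineered <- c(seq_len(16) + 10, seq(0.1, 0.9, length.out = 71))
  expect_equal(sum(classifyRisk(engineered, 5) == "high"), 16L)
})
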