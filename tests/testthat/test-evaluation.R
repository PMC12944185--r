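test_that("one-vs-rest AUC equals brute-force pair counting", {
  expect_equal(ovrAUC(c(0.8, 0.6, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  # tie across the class boundary counts one half
  expect_equal(ovrAUC(c(0.5, 0.5, 0.2), c(1, 0, 0)), 0.75)
  expect_error(ovrAUC(c(0.1, 0.2), c(1, 1)), "undefined-AUC")

  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(ovrAUC(scores, y), oracle_auc_pairs(scores, y))
  }
})

test_that("micro and macro AUC behave as defined", {
  set.seed(8)
  n <- 600
  y <- sample(subtypeLevels(), n, replace = TRUE)
  perfect <- vapply(subtypeLevels(), function(cl) as.numeric(y == cl),
                    numeric(n))
  mm <- microMacroAUC(perfect, y)
  expect_equal(mm$micro, 1)
  expect_equal(mm$macro, 1)

  flat <- matrix(1 / 3, n, 3, dimnames = list(NULL, subtypeLevels()))
  mmf <- microMacroAUC(flat, y)
  expect_equal(mmf$micro, 0.5)
  expect_equal(mmf$macro, 0.5)

  # macro is the mean of the OvR AUCs
  probs <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, subtypeLevels()))
  mm2 <- microMacroAUC(probs, y)
  expect_equal(mm2$macro, mean(mm2$ovr))
  # balanced symmetric scores: micro ~ macro
  expect_lt(abs(mm2$micro - mm2$macro), 0.05)
})

test_that("DeLong test: identical models, cross-check, and bootstrap oracle", {
  set.seed(21)
  n <- 60
  y <- rep(c(TRUE, FALSE), each = 30)
  u <- rnorm(n) + 0.8 * y
  sA <- u + rnorm(n, 0, 0.6)
  sB <- u + rnorm(n, 0, 0.9)

  same <- delongTest(sA, sA, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  dl <- delongTest(sA, sB, y)
  expect_true(dl$p >= 0 && dl$p <= 1)

  # independent implementation cross-check (pROC's DeLong)
  ra <- pROC::roc(y, sA, quiet = TRUE)
  rb <- pROC::roc(y, sB, quiet = TRUE)
  pv <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value
  expect_equal(dl$p, as.numeric(pv), tolerance = 1e-8)

  # paired-bootstrap oracle within +/- 0.02
  pb <- oracle_bootstrap_delong_p(sA, sB, y, reps = 20000, seed = 5)
  expect_lt(abs(dl$p - pb), 0.02)
})

test_that("DeLong variance matches the closed-form null variance on average", {
  # under H0 (continuous scores independent of labels) the exact variance of
  # the empirical AUC is (m + n + 1) / (12 m n)
  m <- 40; n <- 40
  vhat <- vapply(1:300, function(s) {
    set.seed(s)
    y <- rep(c(TRUE, FALSE), c(m, n))
    dl <- delongTest(rnorm(m + n), rnorm(m + n), y)
    # variance of one AUC from the placement covariance (model A slot)
    vA <- var(kineticrad:::.delongPlacements(rnorm(m + n), y)$V10) / m +
      var(kineticrad:::.delongPlacements(rnorm(m + n), y)$V01) / n
    vA
  }, numeric(1))
  expect_equal(mean(vhat), (m + n + 1) / (12 * m * n), tolerance = 0.1)
})

test_that("bootstrap CI: degenerate width, perfect AUC, and coverage", {
  ci0 <- bootstrapCI(function(i) 0.7, 50, reps = 200, seed = 1)
  expect_equal(ci0$lower, ci0$upper)

  set.seed(2)
  y <- rep(c(TRUE, FALSE), each = 25)
  s <- as.numeric(y) + runif(50, 0, 0.5)
  ciP <- bootstrapCI(function(i) {
    yy <- y[i]; if (!any(yy) || all(yy)) stop("missing class")
    ovrAUC(s[i], yy)
  }, 50, reps = 300, seed = 3)
  expect_equal(ciP$upper, 1)

  # coverage of the 95% CI over synthetic cohorts with known true AUC 0.8
  mu <- sqrt(2) * qnorm(0.8)
  cover <- vapply(1:200, function(r) {
    set.seed(r)
    n <- 100
    y <- rbinom(n, 1, 0.5) == 1
    if (!any(y) || all(y)) return(NA)
    s <- rnorm(n) + mu * y
    ci <- bootstrapCI(function(i) {
      yy <- y[i]; if (!any(yy) || all(yy)) stop("missing class")
      kineticrad:::.aucFast(s[i], yy)
    }, n, reps = 1000, seed = r + 10000)
    ci$lower <= 0.8 && 0.8 <= ci$upper
  }, logical(1))
  cov <- mean(cover, na.rm = TRUE)
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.98)
})

test_that("classification report: hand arithmetic and degenerate predictions", {
  cls <- subtypeLevels()
  y <- c(rep(cls[1], 3), rep(cls[2], 7))
  # 2 TP + 1 FN for class 1; 6 TN + 1 FP
  pred <- c(cls[1], cls[1], cls[2], cls[1], rep(cls[2], 6))
  probs <- vapply(cls, function(cl) as.numeric(pred == cl), numeric(10))
  rep_ <- classificationReport(probs, y)
  m1 <- rep_$metrics[rep_$metrics$class == cls[1], ]
  expect_equal(m1$precision, 2 / 3)
  expect_equal(m1$recall, 2 / 3)
  expect_equal(m1$f1, 2 / 3)
  expect_equal(as.numeric(rowSums(rep_$confusion)), c(3, 7, 0))

  # everything predicted one class
  pAll <- matrix(rep(c(1, 0, 0), each = 10), 10, 3,
                 dimnames = list(NULL, cls))
  repA <- classificationReport(pAll, y)
  expect_equal(repA$metrics$recall[1], 1)
  expect_equal(repA$metrics$recall[2], 0)

  # perfect predictions
  probsP <- vapply(cls, function(cl) as.numeric(y == cl), numeric(10))
  repP <- classificationReport(probsP, y)
  expect_true(all(repP$metrics$f1[1:2] == 1))
  expect_equal(sum(diag(repP$confusion)), 10)
})

test_that("calibration curves detect (mis)calibration", {
  set.seed(31)
  n <- 5000
  p <- runif(n)
  y <- rbinom(n, 1, p)
  cc <- calibrationCurve(p, y)
  expect_true(all(abs(cc$observed - cc$meanPredicted) < 0.05))

  ccHalf <- calibrationCurve(rep(0.5, 100), rbinom(100, 1, 0.5))
  expect_equal(nrow(ccHalf), 1)
  expect_equal(ccHalf$meanPredicted, 0.5)

  # injected over-confidence: observed < predicted in the top bins
  pOver <- plogis(3 * qlogis(p))
  ccO <- calibrationCurve(pOver, y)
  top <- ccO$meanPredicted > 0.8
  expect_true(all(ccO$observed[top] < ccO$meanPredicted[top]))
})

test_that("attributions satisfy local accuracy and ignore null players", {
  set.seed(41)
  n <- 250
  y <- sample(subtypeLevels(), n, replace = TRUE)
  X <- data.frame(signal = as.numeric(factor(y, subtypeLevels())) + rnorm(n, 0, 0.3),
                  constant = rep(1, n))
  mdl <- trainBase(X, y, params = boostParams(nRounds = 100), seed = 2)
  att <- attributionSummary(mdl, X)
  for (cl in subtypeLevels()) {
    contrib <- att$perClass[[cl]]
    margin <- qlogis(predictProb(mdl, X, normalize = FALSE)[, cl])
    expect_lt(max(abs(rowSums(contrib) + attr(contrib, "bias") - margin)), 1e-4)
    expect_equal(unname(att$meanAbs["constant", cl]), 0)
    expect_gt(att$meanAbs["signal", cl], 0)
  }
})

test_that("evaluation report assembles consistent pieces", {
  set.seed(55)
  n <- 120
  y <- sample(subtypeLevels(), n, replace = TRUE, prob = c(0.45, 0.35, 0.2))
  probs <- vapply(subtypeLevels(),
                  function(cl) plogis(rnorm(n, ifelse(y == cl, 1, -1))),
                  numeric(n))
  rep_ <- evaluateModel(probs, y, reps = 200, seed = 9)
  expect_s3_class(rep_, "EvaluationReport")
  expect_true(rep_$microAUC["lower"] <= rep_$microAUC["auc"])
  expect_true(rep_$microAUC["auc"] <= rep_$microAUC["upper"])
  expect_true(all(rep_$metrics$support == as.numeric(table(factor(y, subtypeLevels())))))
  expect_named(rep_$ovrAUC, subtypeLevels())
})
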