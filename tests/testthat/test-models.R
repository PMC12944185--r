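test_that("sqrt-balanced weights follow the imbalance arithmetic", {
  y <- c(rep("HR+/HER2-", 299), rep("HER2+", 235), rep("TNBC", 142))
  w <- sqrtBalancedWeights(y)
  expect_equal(unname(w["HR+/HER2-"]), 1)
  expect_equal(unname(w["TNBC"] / w["HR+/HER2-"]), sqrt(299 / 142))
  expect_equal(unname(w["TNBC"]), 1.451, tolerance = 1e-3)
})

test_that("stratified 8:2 split preserves class proportions", {
  y <- c(rep("HR+/HER2-", 374), rep("HER2+", 294), rep("TNBC", 177))
  lab <- data.frame(patient_id = sprintf("p%03d", seq_along(y)), subtype = y)
  sp <- splitCohort(lab, 0.8, seed = 3)
  expect_length(sp$train, 676)
  expect_length(sp$validation, 169)
  expect_length(intersect(sp$train, sp$validation), 0)
  trainCounts <- table(y[sp$train])[subtypeLevels()]
  expect_true(all(abs(as.numeric(trainCounts) - c(299, 235, 142)) <= 1))

  sp2 <- splitCohort(lab, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_error(splitCohort(data.frame(patient_id = 1:8,
                                      subtype = c(rep("TNBC", 4),
                                                  rep("HER2+", 4)))),
               "stratification error")
})

test_that("one-vs-all boosting separates a separable cohort and is deterministic", {
  set.seed(7)
  n <- 300
  y <- sample(subtypeLevels(), n, replace = TRUE, prob = c(0.45, 0.35, 0.2))
  mu <- matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2), 3, byrow = TRUE,
               dimnames = list(subtypeLevels(), NULL))
  X <- as.data.frame(mu[y, ] + matrix(rnorm(n * 3, 0, 0.3), n, 3))
  names(X) <- paste0("f", 1:3)
  mdl <- trainBase(X, y, seed = 2)
  p <- predictProb(mdl, X)
  expect_equal(dim(p), c(n, 3))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  expect_gt(microMacroAUC(p, y)$micro, 0.99)

  mdl2 <- trainBase(X, y, seed = 2)
  expect_identical(predictProb(mdl2, X), p)

  expect_error(trainBase(X, rep("TNBC", n)), "degenerate-training")
})

test_that("pure-noise features give chance-level held-out AUC", {
  aucs <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 240
    y <- sample(subtypeLevels(), n, replace = TRUE)
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    tr <- sample(n, 170)
    mdl <- trainBase(X[tr, ], y[tr], params = boostParams(nRounds = 60),
                     seed = s)
    microMacroAUC(predictProb(mdl, X[-tr, ]), y[-tr])$micro
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("isotonic calibration matches the brute-force monotone fit", {
  ns <- asNamespace("kineticrad")
  # the four-point violator case
  x <- c(0.1, 0.2, 0.3, 0.4); y <- c(0, 1, 0, 1)
  fit <- ns$.isotonicFit(x, y)
  yhat <- ns$.isotonicPredict(fit, x)
  expect_equal(yhat, oracle_isotonic(x, y), tolerance = 1e-12)

  for (s in 1:5) {
    set.seed(s)
    x <- sort(runif(6)); y <- rbinom(6, 1, 0.5)
    fit <- ns$.isotonicFit(x, y)
    expect_equal(ns$.isotonicPredict(fit, x), oracle_isotonic(x, y),
                 tolerance = 1e-12)
  }
})

test_that("calibrators are monotone, bounded, and near-identity when calibrated", {
  set.seed(12)
  n <- 500
  p <- runif(n)
  y <- rbinom(n, 1, p)
  ns <- asNamespace("kineticrad")
  fit <- ns$.isotonicFit(p, y)
  grid <- seq(0.05, 0.95, by = 0.01)
  out <- ns$.isotonicPredict(fit, grid)
  expect_true(all(diff(out) >= -1e-12))
  expect_true(all(out >= 0 & out <= 1))
  expect_lt(mean(abs(out - grid)), 0.05)
})

test_that("fitCalibrators + applyCalibrators keep class columns aligned", {
  set.seed(3)
  n <- 200
  y <- sample(subtypeLevels(), n, replace = TRUE)
  X <- data.frame(f = as.numeric(factor(y, subtypeLevels())) + rnorm(n, 0, 0.4))
  mdl <- trainBase(X, y, params = boostParams(nRounds = 80), seed = 1)
  cal <- fitCalibrators(mdl, X, y)
  expect_s3_class(cal, "CalibratorSet")
  raw <- predictProb(mdl, X, normalize = FALSE)
  calP <- applyCalibrators(cal, raw)
  expect_identical(colnames(calP), subtypeLevels())
  expect_true(all(calP >= 0 & calP <= 1))
  # monotone in the raw score, per class
  for (cl in subtypeLevels()) {
    o <- order(raw[, cl])
    expect_true(all(diff(calP[o, cl]) >= -1e-12))
  }
})

test_that("fusion dominates an informative base when the other is noise", {
  wins <- vapply(1:10, function(s) {
    good <- syntheticCalProbs(260, informative = TRUE, seed = s)
    noise <- syntheticCalProbs(260, informative = FALSE, seed = s + 100)$probs
    tr <- 1:200; te <- 201:260
    fus <- trainFusion(noise[tr, ], good$probs[tr, ], good$labels[tr],
                       params = boostParams(nRounds = 120), seed = s)
    pf <- predictProb(fus, fusionInputs(noise[te, ], good$probs[te, ]))
    base <- microMacroAUC(good$probs[te, ], good$labels[te])$macro
    microMacroAUC(pf, good$labels[te])$macro >= base - 0.03
  }, logical(1))
  expect_gte(mean(wins), 0.8)

  expect_error(trainFusion(matrix(0.5, 5, 3, dimnames = list(NULL, subtypeLevels())),
                           matrix(0.5, 6, 3, dimnames = list(NULL, subtypeLevels())),
                           rep("TNBC", 5)),
               "alignment error")
})

test_that("fusion input order is fixed and recorded", {
  g <- syntheticCalProbs(120, seed = 42)
  noise <- syntheticCalProbs(120, informative = FALSE, seed = 43)$probs
  fus <- trainFusion(noise, g$probs, g$labels,
                     params = boostParams(nRounds = 40), seed = 1)
  X <- fusionInputs(noise, g$probs)
  p1 <- predictProb(fus, X)
  p2 <- predictProb(fus, X[, rev(names(X))])  # permuted columns, same names
  expect_identical(p1, p2)
  expect_identical(fus$featureNames,
                   c(paste0("wir_p_", subtypeLevels()),
                     paste0("area_p_", subtypeLevels())))
})
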