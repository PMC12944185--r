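# One-vs-all boosted subtype models with isotonic probability calibration and
# decision-level fusion. The multiclass one-vs-all loss is realized as three
# independent binary gradient-boosted tree models (one per subtype); each
# class probability is that class's binary model output, renormalized to a
# distribution only where a distribution is required. Class imbalance is
# handled with square-root-balanced sample weights.

#' Square-root-balanced class weights
#'
#' `w_c = sqrt(max_k n_k / n_c)`, the "SqrtBalanced" automatic class
#' weighting rule: minority classes are up-weighted by the square root of
#' their under-representation.
#'
#' @param labels subtype labels.
#' @return named numeric weights, one per class present.
#' @export
sqrtBalancedWeights <- function(labels) {
  n <- table(labels)
  n <- n[n > 0]
  w <- sqrt(max(n) / n)
  stats::setNames(as.numeric(w), names(n))
}

#' Stratified train/validation split
#'
#' @param labels data.frame with `patient_id` and `subtype`, or a factor.
#' @param ratio training fraction (default 0.8, an 8:2 split).
#' @param seed RNG seed; the split is a pure function of `(labels, ratio, seed)`.
#' @return list with `train` and `validation` integer row indices; per-class
#'   proportions are preserved within rounding.
#' @export
splitCohort <- function(labels, ratio = 0.8, seed = 1L) {
  subtype <- if (is.data.frame(labels)) labels$subtype else as.character(labels)
  if (any(table(subtype) < 5L))
    stop("stratification error: every class needs at least 5 patients")
  set.seed(seed)
  train <- integer()
  for (cl in unique(subtype)) {
    idx <- which(subtype == cl)
    nTrain <- round(length(idx) * ratio)
    train <- c(train, sample(idx, nTrain))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(subtype), train))
}

#' Model hyperparameters
#'
#' Boosted-tree settings: depth 6, up to 500 rounds at learning rate 0.05
#' with early stopping on a 10% internal stratified holdout.
#'
#' @param maxDepth,nRounds,eta,earlyStoppingRounds,holdoutFraction see above.
#' @export
boostParams <- function(maxDepth = 6L, nRounds = 500L, eta = 0.05,
                        earlyStoppingRounds = 25L, holdoutFraction = 0.1) {
  list(maxDepth = maxDepth, nRounds = nRounds, eta = eta,
       earlyStoppingRounds = earlyStoppingRounds,
       holdoutFraction = holdoutFraction)
}

#' Train a one-vs-all boosted subtype model
#'
#' Fits one binary gradient-boosted tree model per subtype (positive class
#' vs rest) on the selected feature table, with square-root-balanced sample
#' weights shared across the three binary problems.
#'
#' @param table data.frame of selected features (rows = patients).
#' @param labels subtype labels, one per row.
#' @param sourceType tag recording which image the features came from
#'   (`"TIC-WIR"`, `"TIC-Area"`, `"MR-ORI"`, or `"fusion"`).
#' @param params [boostParams()].
#' @param seed RNG seed (internal holdout split); training is deterministic
#'   given the seed.
#'
#' @return a `SubtypeModel` list: per-class boosters, class order, feature
#'   names, weights, seed.
#' @export
trainBase <- function(table, labels, sourceType = "TIC-WIR",
                      params = boostParams(), seed = 1L) {
  labels <- factor(labels, levels = subtypeLevels())
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("degenerate-training error: need at least 2 classes")
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  w <- sqrtBalancedWeights(labels)
  sw <- as.numeric(w[as.character(labels)])

  set.seed(seed)
  n <- nrow(X)
  hold <- integer()
  for (cl in levels(labels)) {  # stratified internal holdout for early stopping
    idx <- which(labels == cl)
    nh <- max(1L, round(length(idx) * params$holdoutFraction))
    hold <- c(hold, sample(idx, nh))
  }
  fit <- seq_len(n)[-hold]

  boosters <- list()
  for (cl in levels(labels)) {
    y <- as.numeric(labels == cl)
    dfit <- xgboost::xgb.DMatrix(X[fit, , drop = FALSE], label = y[fit],
                                 weight = sw[fit])
    dhold <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = y[hold],
                                  weight = sw[hold])
    boosters[[cl]] <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$maxDepth,
                    eta = params$eta, nthread = 1, seed = seed,
                    eval_metric = "logloss"),
      data = dfit, nrounds = params$nRounds,
      evals = list(holdout = dhold),
      early_stopping_rounds = params$earlyStoppingRounds, verbose = 0)
  }
  structure(list(boosters = boosters, classes = levels(labels),
                 featureNames = colnames(X), weights = w, seed = seed,
                 sourceType = sourceType, params = params),
            class = "SubtypeModel")
}

#' Predict class probabilities from a SubtypeModel
#'
#' @param model a `SubtypeModel`.
#' @param table feature data.frame with the model's feature columns.
#' @param normalize if `TRUE` (default) the three one-vs-all probabilities
#'   are renormalized to sum to 1; raw per-class probabilities (the
#'   calibrators' input) are returned with `normalize = FALSE`.
#' @return numeric matrix (rows = patients, columns = classes).
#' @export
predictProb <- function(model, table, normalize = TRUE) {
  stopifnot(inherits(model, "SubtypeModel"))
  X <- as.matrix(table[, model$featureNames, drop = FALSE])
  storage.mode(X) <- "double"
  p <- vapply(model$classes,
              function(cl) stats::predict(model$boosters[[cl]],
                                           xgboost::xgb.DMatrix(X)),
              numeric(nrow(X)))
  p <- matrix(p, nrow = nrow(X),
              dimnames = list(rownames(table), model$classes))
  if (normalize) p <- p / pmax(rowSums(p), .Machine$double.eps)
  p
}

#' Fit per-class isotonic calibrators
#'
#' For each class `c`, fits a monotone nondecreasing map from the model's
#' raw one-vs-all probability for `c` to a calibrated probability, by
#' pool-adjacent-violators regression of the indicator `1{y = c}` on
#' training-set predictions. With `method = "cv"` (the default) the
#' predictions are cross-validated within the training set — fold models of
#' the same family score their held-out fold — which avoids the degenerate
#' near-binary calibration that in-sample predictions of a well-fitting
#' model produce; `method = "insample"` uses the final model's own training
#' predictions. Either way the learned maps are frozen and applied unchanged
#' to validation data.
#'
#' @param model a `SubtypeModel`.
#' @param table training feature table.
#' @param labels training labels.
#' @param method `"cv"` or `"insample"`.
#' @param folds calibration folds for `method = "cv"`.
#' @param seed RNG seed for the calibration fold split.
#' @return a `CalibratorSet` list of per-class knot tables.
#' @export
fitCalibrators <- function(model, table, labels, method = c("cv", "insample"),
                           folds = 5L, seed = model$seed) {
  method <- match.arg(method)
  labels <- factor(labels, levels = model$classes)
  if (method == "insample") {
    raw <- predictProb(model, table, normalize = FALSE)
  } else {
    set.seed(seed)
    foldid <- integer(nrow(table))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      foldid[idx] <- rep_len(seq_len(folds), length(idx))
    }
    raw <- matrix(NA_real_, nrow(table), length(model$classes),
                  dimnames = list(rownames(table), model$classes))
    for (k in seq_len(folds)) {
      inFold <- foldid == k
      fm <- trainBase(table[!inFold, , drop = FALSE], labels[!inFold],
                      sourceType = model$sourceType, params = model$params,
                      seed = seed + k)
      raw[inFold, ] <- predictProb(fm, table[inFold, , drop = FALSE],
                                   normalize = FALSE)
    }
  }
  cal <- lapply(model$classes, function(cl) {
    .isotonicFit(raw[, cl], as.numeric(labels == cl))
  })
  names(cal) <- model$classes
  structure(cal, class = "CalibratorSet")
}

# pool-adjacent-violators least-squares monotone fit; returns knots (unique
# sorted x with the fitted value at each)
.isotonicFit <- function(x, y) {
  o <- order(x, y)
  fit <- stats::isoreg(x[o], y[o])
  xf <- fit$x
  yf <- fit$yf
  ux <- unique(xf)
  uy <- vapply(ux, function(v) yf[max(which(xf == v))], numeric(1))
  list(x = ux, y = pmin(pmax(uy, 0), 1))
}

.isotonicPredict <- function(knots, xnew) {
  if (length(knots$x) == 1L) return(rep(knots$y, length(xnew)))
  stats::approx(knots$x, knots$y, xout = xnew, method = "linear", rule = 2)$y
}

#' @describeIn fitCalibrators fit the per-class isotonic maps directly from a
#'   matrix of raw one-vs-all probabilities (columns named by class), e.g.
#'   out-of-fold predictions produced by a nested resampling scheme.
#' @param rawProbs matrix of raw per-class probabilities.
#' @export
fitCalibratorsRaw <- function(rawProbs, labels) {
  classes <- colnames(rawProbs)
  labels <- factor(labels, levels = classes)
  cal <- lapply(classes, function(cl)
    .isotonicFit(rawProbs[, cl], as.numeric(labels == cl)))
  names(cal) <- classes
  structure(cal, class = "CalibratorSet")
}

#' Apply a CalibratorSet to raw probabilities
#'
#' @param calibrators a `CalibratorSet` from [fitCalibrators()].
#' @param rawProbs matrix of raw one-vs-all probabilities (columns = classes).
#' @return matrix of calibrated per-class probabilities. These are *not*
#'   renormalized: each column is individually calibrated and the set is used
#'   as features by the fusion model, not as a distribution.
#' @export
applyCalibrators <- function(calibrators, rawProbs) {
  stopifnot(inherits(calibrators, "CalibratorSet"))
  out <- vapply(names(calibrators),
                function(cl) .isotonicPredict(calibrators[[cl]], rawProbs[, cl]),
                numeric(nrow(rawProbs)))
  matrix(out, nrow = nrow(rawProbs),
         dimnames = list(rownames(rawProbs), names(calibrators)))
}

#' Train the decision-level fusion model
#'
#' Stacks the six calibrated probabilities (three per base model) as input
#' features of a boosted-tree meta-classifier of the same family as the base
#' models. The input column order is fixed and recorded in the model.
#'
#' @param wirCalProbs,areaCalProbs calibrated probability matrices from the
#'   TIC-WIR and TIC-Area models, row-aligned with `labels`.
#' @param labels subtype labels.
#' @param params,seed as in [trainBase()]; the meta-classifier defaults to
#'   shallower trees (depth 3) than the base models, matching its 6-column
#'   input.
#' @return a `SubtypeModel` with `sourceType = "fusion"`.
#' @export
trainFusion <- function(wirCalProbs, areaCalProbs, labels,
                        params = boostParams(maxDepth = 3L), seed = 1L) {
  if (nrow(wirCalProbs) != nrow(areaCalProbs) ||
      nrow(wirCalProbs) != length(labels))
    stop("alignment error: probability matrices and labels differ in rows")
  X <- fusionInputs(wirCalProbs, areaCalProbs)
  trainBase(X, labels, sourceType = "fusion", params = params, seed = seed)
}

#' @describeIn trainFusion assemble the fixed-order 6-column fusion input.
#' @export
fusionInputs <- function(wirCalProbs, areaCalProbs) {
  cls <- subtypeLevels()
  X <- cbind(wirCalProbs[, cls, drop = FALSE], areaCalProbs[, cls, drop = FALSE])
  colnames(X) <- c(paste0("wir_p_", cls), paste0("area_p_", cls))
  as.data.frame(X)
}
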