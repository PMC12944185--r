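# Multiclass ROC statistics: one-vs-rest / micro / macro AUC, DeLong
# comparisons of paired AUCs, percentile bootstrap CIs, confusion-matrix
# metrics, calibration curves, and additive (TreeSHAP) attributions.

#' One-vs-rest AUC
#'
#' Mann-Whitney AUC of the class score against the binarized labels; ties
#' across the class boundary count 1/2 (midranks).
#'
#' @param scores numeric scores (higher = more positive), or a probability
#'   matrix together with `class`.
#' @param labels labels; binarized as `labels == class` when `class` given,
#'   otherwise must already be 0/1 or logical.
#' @param class optional class name.
#' @return the AUC.
#' @export
ovrAUC <- function(scores, labels, class = NULL) {
  if (!is.null(class)) {
    if (is.matrix(scores) || is.data.frame(scores))
      scores <- as.matrix(scores)[, class]
    labels <- labels == class
  }
  y <- as.logical(labels)
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("undefined-AUC error: both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# lean AUC without checks (bootstrap/oracle inner loops)
.aucFast <- function(scores, y) {
  nPos <- sum(y)
  (sum(rank(scores)[y]) - nPos * (nPos + 1) / 2) / (nPos * (length(y) - nPos))
}

#' Micro- and macro-average multiclass AUC
#'
#' Macro: mean of the per-class one-vs-rest AUCs. Micro: AUC over the
#' flattened (sample, class) binary problem, i.e. all `n * K` class scores
#' against the `n * K` one-hot indicators.
#'
#' @param probs probability/score matrix, columns named by class.
#' @param labels true labels.
#' @return list with `micro`, `macro` and `ovr` (named per-class AUCs).
#' @export
microMacroAUC <- function(probs, labels) {
  probs <- as.matrix(probs)
  cls <- colnames(probs)
  ovr <- vapply(cls, function(cl) ovrAUC(probs[, cl], labels, cl), numeric(1))
  flatScores <- as.vector(probs)
  flatLabels <- as.vector(vapply(cls, function(cl) labels == cl,
                                 logical(length(labels))))
  list(micro = ovrAUC(flatScores, flatLabels), macro = mean(ovr), ovr = ovr)
}

#' DeLong test for paired AUCs
#'
#' Compares the empirical AUCs of two models scoring the same samples, using
#' the placement-value covariance estimate and a two-sided normal reference.
#' When the estimated variance of the AUC difference is (numerically) zero
#' and the AUCs are equal, `z = 0, p = 1` by convention.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels binary labels (logical or 0/1).
#' @return list with `aucA`, `aucB`, `z`, `p`, `varDiff`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("undefined-AUC error: both classes required")
  m <- sum(y); n <- sum(!y)
  pA <- .delongPlacements(scoresA, y)
  pB <- .delongPlacements(scoresB, y)
  auc <- c(pA$auc, pB$auc)
  V10 <- cbind(pA$V10, pB$V10)  # placement values of positives
  V01 <- cbind(pA$V01, pB$V01)  # placement values of negatives
  S10 <- stats::cov(V10); S01 <- stats::cov(V01)
  Svar <- S10 / m + S01 / n
  varDiff <- Svar[1, 1] + Svar[2, 2] - 2 * Svar[1, 2]
  if (varDiff <= .Machine$double.eps) {
    z <- if (abs(auc[1] - auc[2]) < .Machine$double.eps) 0 else Inf * sign(auc[1] - auc[2])
  } else {
    z <- (auc[1] - auc[2]) / sqrt(varDiff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(aucA = auc[1], aucB = auc[2], z = z, p = p, varDiff = varDiff)
}

# placement values of one score vector: V10[i] = fraction of negatives each
# positive outranks (ties 1/2), V01[j] likewise for negatives
.delongPlacements <- function(scores, y) {
  m <- sum(y); n <- sum(!y)
  x <- scores[y]; z <- scores[!y]
  rAll <- rank(c(x, z))
  V10 <- (rAll[seq_len(m)] - rank(x)) / n
  V01 <- 1 - (rAll[m + seq_len(n)] - rank(z)) / m
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients (rows) with replacement and recomputes the metric;
#' resamples on which the metric is undefined (e.g. a class missing) are
#' skipped and counted, and more than 10% skips is an error.
#'
#' @param metricFn function(indices) -> scalar; receives the resampled row
#'   indices so that all per-patient quantities stay together.
#' @param n number of patients.
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `skipped`.
#' @export
bootstrapCI <- function(metricFn, n, reps = 1000L, seed = 1L, level = 0.95) {
  set.seed(seed)
  vals <- numeric(reps)
  skipped <- 0L
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(metricFn(idx), error = function(e) NA_real_)
    if (is.na(v)) skipped <- skipped + 1L else vals[b - skipped] <- v
  }
  if (skipped > 0.1 * reps)
    stop("unstable-CI error: ", skipped, "/", reps, " resamples skipped")
  vals <- vals[seq_len(reps - skipped)]
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  list(lower = q[1], upper = q[2], skipped = skipped)
}

#' Confusion matrix and per-class precision/recall/F1
#'
#' Argmax decision rule; rows are true classes in canonical subtype order,
#' columns predicted classes. Precision/recall/F1 are 0 when their
#' denominator is 0.
#'
#' @param probs probability matrix (columns named by class).
#' @param labels true labels.
#' @return list with `confusion` and `metrics` (data.frame).
#' @export
classificationReport <- function(probs, labels) {
  probs <- as.matrix(probs)
  cls <- colnames(probs)
  pred <- cls[max.col(probs, ties.method = "first")]
  conf <- table(factor(labels, levels = cls), factor(pred, levels = cls))
  names(dimnames(conf)) <- c("true", "predicted")
  prec <- rec <- f1 <- numeric(length(cls))
  for (k in seq_along(cls)) {
    tp <- conf[k, k]
    prec[k] <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec[k] <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(confusion = conf,
       metrics = data.frame(class = cls, precision = prec, recall = rec,
                            f1 = f1, support = as.numeric(rowSums(conf))))
}

#' Reliability (calibration) curve
#'
#' Equal-width bins on the predicted probability; per occupied bin, the mean
#' predicted probability and the observed event frequency. Bins with fewer
#' than 5 samples are flagged.
#'
#' @param probs predicted probabilities for one class.
#' @param labels binary outcomes (logical or 0/1).
#' @param nBins number of equal-width bins (default 10).
#' @return data.frame with `binMid`, `meanPredicted`, `observed`, `n`,
#'   `lowCount`.
#' @export
calibrationCurve <- function(probs, labels, nBins = 10L) {
  y <- as.numeric(labels)
  bin <- pmin(pmax(ceiling(probs * nBins), 1L), nBins)
  occupied <- sort(unique(bin))
  data.frame(
    binMid = (occupied - 0.5) / nBins,
    meanPredicted = vapply(occupied, function(b) mean(probs[bin == b]), numeric(1)),
    observed = vapply(occupied, function(b) mean(y[bin == b]), numeric(1)),
    n = vapply(occupied, function(b) sum(bin == b), numeric(1)),
    lowCount = vapply(occupied, function(b) sum(bin == b) < 5, logical(1))
  )
}

#' Additive feature attributions (TreeSHAP) for a SubtypeModel
#'
#' Exact tree-ensemble Shapley attributions of each class's one-vs-all
#' margin (log-odds). Attributions satisfy local accuracy: per sample the
#' attributions plus the bias term sum to the model's margin output.
#'
#' @param model a `SubtypeModel`.
#' @param table feature table.
#' @return list with `perClass` (list of sample x feature matrices, bias in
#'   attribute `"bias"`) and `meanAbs` (feature x class matrix of mean
#'   absolute attributions).
#' @export
attributionSummary <- function(model, table) {
  stopifnot(inherits(model, "SubtypeModel"))
  X <- as.matrix(table[, model$featureNames, drop = FALSE])
  storage.mode(X) <- "double"
  perClass <- list()
  meanAbs <- matrix(0, ncol(X), length(model$classes),
                    dimnames = list(model$featureNames, model$classes))
  for (cl in model$classes) {
    ct <- stats::predict(model$boosters[[cl]], xgboost::xgb.DMatrix(X),
                         predcontrib = TRUE)
    contrib <- ct[, seq_len(ncol(X)), drop = FALSE]
    colnames(contrib) <- model$featureNames
    attr(contrib, "bias") <- ct[, ncol(ct)]
    perClass[[cl]] <- contrib
    meanAbs[, cl] <- colMeans(abs(contrib))
  }
  list(perClass = perClass, meanAbs = meanAbs)
}

#' Full evaluation report for one model on one dataset
#'
#' @param probs probability matrix (columns named by class).
#' @param labels true labels.
#' @param reps bootstrap replicates for the AUC CIs (default 1000);
#'   `reps = 0` skips the CIs (NA bounds), for datasets too small to
#'   resample stably.
#' @param seed RNG seed for the bootstrap.
#' @return an `EvaluationReport` list: `microAUC`, `macroAUC`, `ovrAUC`
#'   (each with 95% percentile bootstrap CI), `confusion`, `metrics`,
#'   `calibration` (per-class curves).
#' @export
evaluateModel <- function(probs, labels, reps = 1000L, seed = 1L) {
  probs <- as.matrix(probs)
  cls <- colnames(probs)
  aucs <- microMacroAUC(probs, labels)
  ciOf <- function(fn, s) {
    if (reps <= 0) return(list(lower = NA_real_, upper = NA_real_, skipped = 0L))
    bootstrapCI(fn, length(labels), reps, s)
  }
  microCI <- ciOf(function(i) microMacroAUC(probs[i, , drop = FALSE], labels[i])$micro, seed)
  macroCI <- ciOf(function(i) microMacroAUC(probs[i, , drop = FALSE], labels[i])$macro, seed + 1L)
  ovr <- list()
  for (k in seq_along(cls)) {
    ci <- ciOf(function(i) ovrAUC(probs[i, cls[k]], labels[i], cls[k]), seed + 1L + k)
    ovr[[cls[k]]] <- c(auc = unname(aucs$ovr[cls[k]]),
                       lower = ci$lower, upper = ci$upper)
  }
  rep_ <- classificationReport(probs, labels)
  calib <- lapply(cls, function(cl) calibrationCurve(probs[, cl], labels == cl))
  names(calib) <- cls
  structure(list(
    microAUC = c(auc = aucs$micro, lower = microCI$lower, upper = microCI$upper),
    macroAUC = c(auc = aucs$macro, lower = macroCI$lower, upper = macroCI$upper),
    ovrAUC = ovr, confusion = rep_$confusion, metrics = rep_$metrics,
    calibration = calib, n = length(labels)
  ), class = "EvaluationReport")
}

#' Micro-average DeLong comparison of two models
#'
#' Applies the DeLong test to the flattened (sample, class) scores, the same
#' units the micro-average AUC is computed over. The within-patient
#' correlation across the three flattened entries is not modeled; see the
#' package vignette for the caveat.
#'
#' @param probsA,probsB probability matrices (same columns).
#' @param labels true labels.
#' @return [delongTest()] result.
#' @export
compareModelsMicro <- function(probsA, probsB, labels) {
  probsA <- as.matrix(probsA); probsB <- as.matrix(probsB)
  cls <- colnames(probsA)
  flatLabels <- as.vector(vapply(cls, function(cl) labels == cl,
                                 logical(length(labels))))
  delongTest(as.vector(probsA), as.vector(probsB[, cls]), flatLabels)
}
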