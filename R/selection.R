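# Three-step feature selection, fit on training rows only and then frozen:
# (1) remove features with raw sample variance below 0.01, (2) iteratively
# prune correlated pairs (|r| > 0.8), dropping the member with the higher
# mean absolute correlation to all remaining features, (3) z-score and run
# L1-penalized multinomial logistic regression with stratified 10-fold CV,
# keeping the union of nonzero supports at lambda.min. Applying the frozen
# result to new data touches only column names.

#' Low-variance filter
#'
#' @param table data.frame of features (rows = patients).
#' @param threshold features with sample variance strictly below this are
#'   removed; applied to the raw (un-standardized) feature values.
#' @return list with `kept` and `removed` column names.
#' @export
varianceFilter <- function(table, threshold = 0.01) {
  stopifnot(nrow(table) >= 2)
  v <- vapply(table, stats::var, numeric(1))
  kept <- names(v)[v >= threshold]
  if (length(kept) == 0L)
    stop("selection-collapse error: variance filter removed every feature")
  list(kept = kept, removed = setdiff(names(v), kept))
}

#' Correlation pruning
#'
#' Repeatedly finds the remaining pair with the largest absolute Pearson
#' correlation exceeding `rMax` and drops the pair member whose mean absolute
#' correlation to all remaining features is higher (ties: the later column),
#' until no pair exceeds the threshold.
#'
#' @param table data.frame of features.
#' @param rMax absolute correlation threshold (default 0.8).
#' @return list with `kept` and `removed` column names.
#' @export
correlationPrune <- function(table, rMax = 0.8) {
  nm <- names(table)
  if (length(nm) < 2L) return(list(kept = nm, removed = character()))
  cm <- abs(stats::cor(as.matrix(table)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(cm))
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (all(sub <= rMax)) break
    top <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    meanAbs <- rowMeans(sub)
    i <- top[1]; j <- top[2]
    drop_local <- if (meanAbs[i] > meanAbs[j]) i
      else if (meanAbs[j] > meanAbs[i]) j
      else max(i, j)  # tie: drop the later column
    alive[which(alive)[drop_local]] <- FALSE
  }
  list(kept = nm[alive], removed = nm[!alive])
}

#' LASSO feature selection
#'
#' Z-scores the features (training mean/sd) and fits an L1-penalized
#' multinomial logistic regression; the penalty is chosen by stratified
#' k-fold cross-validation minimizing the mean multinomial deviance, and the
#' selected set is the union of features with a nonzero coefficient for any
#' class at that penalty.
#'
#' @param table data.frame of features (already variance/correlation pruned).
#' @param labels subtype labels, one per row.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @return list with `kept`, `removed`, `lambda`, `center`, `scale`.
#' @export
lassoSelect <- function(table, labels, folds = 10, seed = 1L) {
  labels <- factor(labels, levels = subtypeLevels())
  if (any(table(labels) < folds))
    stop("stratification error: every class needs at least ", folds, " rows")
  X <- as.matrix(table)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  set.seed(seed)
  foldid <- integer(nrow(X))
  for (cl in levels(labels)) {   # stratified fold assignment
    idx <- sample(which(labels == cl))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  # glmnet warns about small per-class counts inside CV folds; that is the
  # expected regime for radiomics cohorts, so muffle that one message
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(Xs, labels, family = "multinomial",
                      type.measure = "deviance", foldid = foldid,
                      standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # lambda at the CV deviance minimum; if that support is empty (weak-signal
  # tables), the best-CV lambda among those keeping at least one feature
  lambda <- cv$lambda.min
  if (cv$nzero[cv$lambda == lambda] == 0) {
    ok <- which(cv$nzero > 0)
    if (length(ok) == 0L)
      stop("selection-collapse error: LASSO removed every feature")
    lambda <- cv$lambda[ok[which.min(cv$cvm[ok])]]
  }
  cf <- glmnet::coef.glmnet(cv$glmnet.fit, s = lambda)
  nz <- Reduce(`|`, lapply(cf, function(b) as.vector(b[-1, 1]) != 0))
  kept <- colnames(X)[nz]
  if (length(kept) == 0L)
    stop("selection-collapse error: LASSO removed every feature")
  list(kept = kept, removed = setdiff(colnames(X), kept),
       lambda = lambda, center = ctr[kept], scale = scl[kept])
}

#' Full three-step selection
#'
#' @inheritParams lassoSelect
#' @param varThreshold variance threshold (step 1).
#' @param rMax correlation threshold (step 2).
#' @return a `SelectionResult` list: `keptFeatures` (ordered),
#'   `varianceRemoved`, `correlationRemoved`, `lassoRemoved`, `lassoLambda`,
#'   and the z-scoring `center`/`scale` of the kept features. The three
#'   removal sets plus `keptFeatures` partition the input columns.
#' @export
selectFeatures <- function(table, labels, varThreshold = 0.01, rMax = 0.8,
                           folds = 10, seed = 1L) {
  s1 <- varianceFilter(table, varThreshold)
  s2 <- correlationPrune(table[, s1$kept, drop = FALSE], rMax)
  s3 <- lassoSelect(table[, s2$kept, drop = FALSE], labels, folds, seed)
  structure(
    list(keptFeatures = s3$kept,
         varianceRemoved = s1$removed,
         correlationRemoved = s2$removed,
         lassoRemoved = s3$removed,
         lassoLambda = s3$lambda,
         center = s3$center, scale = s3$scale),
    class = "SelectionResult"
  )
}

#' Apply a frozen selection to a feature table
#'
#' @param selection a `SelectionResult`.
#' @param table data.frame with at least the selected columns.
#' @return data.frame restricted to the selected columns, in selection order.
#' @export
applySelection <- function(selection, table) {
  stopifnot(inherits(selection, "SelectionResult"))
  missing <- setdiff(selection$keptFeatures, names(table))
  if (length(missing))
    stop("feature table lacks selected columns: ",
         paste(utils::head(missing, 3), collapse = ", "))
  table[, selection$keptFeatures, drop = FALSE]
}

#' @describeIn selectFeatures serialize a SelectionResult to JSON.
#' @param selection a `SelectionResult`.
#' @param path output file.
#' @export
writeSelection <- function(selection, path) {
  jsonlite::write_json(unclass(selection), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
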