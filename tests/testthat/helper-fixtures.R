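# shared fixture builders (everything generated in code)

# uniform-intensity series from scalar phase values
constSeries <- function(pre, posts, times = c(60, 120, 180, 240, 300),
                        d = c(4, 4, 3)) {
  DCESeries(array(pre, d), lapply(posts, function(v) array(v, d)), times)
}

smallSpec <- function(...) {
  phantomSpec(nPerClass = c(2L, 2L, 2L), gridShape = c(24L, 24L, 24L),
              lesionRadii = c(4, 5.5), ...)
}

# compact kinetics for WIR-recovery checks: both classes peak at a sampled
# phase inside the first three
twoLevelKinetics <- function(wA = 0.02, wB = 0.005) {
  k <- defaultClassKinetics()
  k[["HR+/HER2-"]]$washinMean <- wB
  k[["HR+/HER2-"]]$washinSD <- 0.1 * wB
  k[["HR+/HER2-"]]$tPeak <- 120
  k[["HER2+"]]$washinMean <- (wA + wB) / 2
  k[["TNBC"]]$washinMean <- wA
  k[["TNBC"]]$washinSD <- 0.1 * wA
  k[["TNBC"]]$tPeak <- 120
  k
}

# probability-level synthetic "calibrated outputs" for fusion-level tests:
# informative columns from a latent class signal, noise columns uniform
syntheticCalProbs <- function(n, informative = TRUE, sd = 0.6, seed = 1) {
  set.seed(seed)
  cls <- subtypeLevels()
  y <- factor(sample(cls, n, replace = TRUE, prob = c(0.45, 0.35, 0.2)),
              levels = cls)
  p <- matrix(runif(n * 3, 0.05, 0.95), n, 3, dimnames = list(NULL, cls))
  if (informative) {
    for (k in seq_along(cls)) {
      z <- rnorm(n, ifelse(y == cls[k], 1.2, -1.2), sd * 2)
      p[, k] <- plogis(z)
    }
  }
  list(probs = p, labels = as.character(y))
}
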