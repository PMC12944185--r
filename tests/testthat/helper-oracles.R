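# Brute-force oracles used across the suite. Everything here is written as
# direct enumeration, independently of the package's vectorized/compiled
# implementations.

# all 26 neighbor offsets and the 13 unique direction representatives
oracle_offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
oracle_dirs13 <- function() {
  g <- oracle_offsets26()
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

oracle_inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric co-occurrence counts for one direction, by looping voxel pairs
oracle_glcm_counts <- function(lev, off) {
  d <- dim(lev)
  L <- max(lev)
  M <- matrix(0, L, L)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + off
    if (!oracle_inGrid(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# zones of 26-connected equal-level voxels via BFS over coordinates
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  offs <- oracle_offsets26()
  out <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (oracle_inGrid(q, d) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    out <- rbind(out, c(g, size))
  }
  out
}

# run-length enumeration for one direction: walk forward from run starts
oracle_runs <- function(lev, dir) {
  d <- dim(lev)
  out <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lev[x, y, z]
    if (g == 0) next
    p <- c(x, y, z) - dir
    if (oracle_inGrid(p, d) && lev[p[1], p[2], p[3]] == g) next  # not a start
    len <- 0
    q <- c(x, y, z)
    while (oracle_inGrid(q, d) && lev[q[1], q[2], q[3]] == g) {
      len <- len + 1
      q <- q + dir
    }
    out <- rbind(out, c(g, len))
  }
  out
}

# per-voxel dependence (equal-level 26-neighbors + center) and NGTDM stats
oracle_dependence <- function(lev) {
  d <- dim(lev)
  offs <- oracle_offsets26()
  out <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lev[x, y, z]
    if (g == 0) next
    dep <- 1
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (oracle_inGrid(q, d) && lev[q[1], q[2], q[3]] == g) dep <- dep + 1
    }
    out <- rbind(out, c(g, dep))
  }
  out
}

oracle_ngtdm_stats <- function(lev) {
  d <- dim(lev)
  offs <- oracle_offsets26()
  gvals <- sort(unique(lev[lev > 0]))
  ni <- setNames(numeric(length(gvals)), gvals)
  si <- setNames(numeric(length(gvals)), gvals)
  nvp <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    g <- lev[x, y, z]
    if (g == 0) next
    nb <- c()
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (oracle_inGrid(q, d) && lev[q[1], q[2], q[3]] > 0)
        nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    ni[as.character(g)] <- ni[as.character(g)] + 1
    si[as.character(g)] <- si[as.character(g)] + abs(g - mean(nb))
  }
  list(g = gvals, ni = as.numeric(ni), si = as.numeric(si), nvp = nvp)
}

## independently written formulas for the named texture features -------------

oracle_glcm_sum_entropy <- function(counts) {
  present <- which(rowSums(counts) > 0)
  P <- counts[present, present, drop = FALSE] / sum(counts)
  ps <- c()
  for (i in seq_along(present)) for (j in seq_along(present)) {
    k <- as.character(present[i] + present[j])
    ps[k] <- if (is.null(ps[k]) || is.na(ps[k])) P[i, j] else ps[k] + P[i, j]
  }
  -sum(ps[ps > 0] * log2(ps[ps > 0]))
}

# generic zone/run/dependence-style oracle features from an observation list
# of (gray level, size) rows
oracle_size_features <- function(obs, np) {
  g <- obs[, 1]; s <- obs[, 2]
  N <- nrow(obs)
  list(
    GrayLevelNonUniformityNormalized =
      sum((table(g) / N)^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    SmallAreaEmphasis = mean(1 / s^2),
    LargeDependenceLowGrayLevelEmphasis = mean(s^2 / g^2),
    DependenceVariance = {
      mu <- mean(s); mean((s - mu)^2)
    },
    GrayLevelNonUniformity = sum(table(g)^2) / N,
    ZonePercentage = N / np
  )
}

oracle_ngtdm_busyness <- function(lev) {
  st <- oracle_ngtdm_stats(lev)
  p <- st$ni / st$nvp
  if (length(st$g) <= 1) return(0)
  num <- sum(p * st$si)
  den <- 0
  for (i in seq_along(st$g)) for (j in seq_along(st$g)) {
    if (p[i] > 0 && p[j] > 0)
      den <- den + abs(st$g[i] * p[i] - st$g[j] * p[j])
  }
  if (den == 0) 0 else num / den
}

## statistics oracles ---------------------------------------------------------

# AUC by exhaustive pair counting, ties = 1/2
oracle_auc_pairs <- function(scores, y) {
  pos <- scores[as.logical(y)]
  neg <- scores[!as.logical(y)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# least-squares monotone (nondecreasing) step fit by exhaustive enumeration
# of consecutive-block partitions; returns fitted values
oracle_isotonic <- function(x, y) {
  o <- order(x)
  y <- y[o]
  n <- length(y)
  best <- NULL; bestSSE <- Inf
  for (code in 0:(2^(n - 1) - 1)) {           # bit k set = cut after point k
    cuts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- mean(y[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum((y - fit)^2)
    if (sse < bestSSE - 1e-12) { bestSSE <- sse; best <- fit }
  }
  best[order(o)]
}

# paired bootstrap two-sided p-value for the AUC difference of two models
oracle_bootstrap_delong_p <- function(sA, sB, y, reps = 20000, seed = 1) {
  set.seed(seed)
  y <- as.logical(y)
  n <- length(y)
  auc <- function(s, yy) {
    np <- sum(yy)
    (sum(rank(s)[yy]) - np * (np + 1) / 2) / (np * (length(yy) - np))
  }
  diffs <- numeric(reps)
  kept <- 0
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    yy <- y[idx]
    if (!any(yy) || all(yy)) next
    kept <- kept + 1
    diffs[kept] <- auc(sA[idx], yy) - auc(sB[idx], yy)
  }
  diffs <- diffs[seq_len(kept)]
  2 * min(mean(diffs <= 0), mean(diffs >= 0))
}

# direct triple-loop separable 3D convolution with half-sample symmetric
# reflection (wavelet oracle)
oracle_conv3d <- function(img, kx, ky, kz) {
  d <- dim(img)
  refl <- function(p, n) {
    if (p < 1) p <- 1 - p else if (p > n) p <- 2 * n + 1 - p
    if (p < 1 || p > n) refl(p, n) else p
  }
  shift <- function(k) length(k) %/% 2
  out <- array(0, dim = d)
  sx <- shift(kx); sy <- shift(ky); sz <- shift(kz)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0
    for (a in seq_along(kx)) for (b in seq_along(ky)) for (cc in seq_along(kz)) {
      px <- refl(x + (a - 1) - sx, d[1])
      py <- refl(y + (b - 1) - sy, d[2])
      pz <- refl(z + (cc - 1) - sz, d[3])
      acc <- acc + kx[a] * ky[b] * kz[cc] * img[px, py, pz]
    }
    out[x, y, z] <- acc
  }
  out
}

# small random ROI fixture: levels 1..L on part of a grid
oracle_random_roi <- function(d = c(5, 5, 3), L = 4, fillProb = 0.8, seed = 1) {
  set.seed(seed)
  lev <- array(0L, dim = d)
  inm <- array(runif(prod(d)) < fillProb, dim = d)
  lev[inm] <- sample.int(L, sum(inm), replace = TRUE)
  lev
}
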