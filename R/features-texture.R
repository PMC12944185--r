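# Gray-level texture matrices and their features, computed on the fixed-bin
# discretized ROI (integer level array with 0 outside the mask). Conventions:
# 26-connectivity / 13 unique 3D directions at distance 1, symmetric GLCM
# with features averaged over directions, GLRLM averaged over directions,
# gray values in formulas are the actual discretized level values with empty
# levels removed, dependence counts include the center voxel. Zero-variance
# degenerate cases return the conventional values noted inline so a feature
# table never contains NaN.

.directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# level values of all valid in-grid voxel pairs separated by `off`
.shiftPairs <- function(lev, off) {
  d <- dim(lev)
  xr <- max(1, 1 - off[1]):min(d[1], d[1] - off[1])
  yr <- max(1, 1 - off[2]):min(d[2], d[2] - off[2])
  zr <- max(1, 1 - off[3]):min(d[3], d[3] - off[3])
  list(a = as.vector(lev[xr, yr, zr]),
       b = as.vector(lev[xr + off[1], yr + off[2], zr + off[3]]))
}

.zoneSizes <- function(lev) {
  .cpp_zone_sizes(as.integer(lev), dim(lev))
}

## ---- GLCM -----------------------------------------------------------------

glcmFeatureNames <- function() c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

# features from one raw (unnormalized, symmetric) co-occurrence count matrix
# whose rows/cols are levels 1..Lmax; empty levels are dropped and formulas
# use the surviving actual gray values.
.glcmFromCounts <- function(counts) {
  present <- which(rowSums(counts) + colSums(counts) > 0)
  P <- counts[present, present, drop = FALSE]
  g <- as.numeric(present)
  P <- P / sum(P)
  Ng <- length(g)
  px <- rowSums(P)
  mu <- sum(g * px)
  sigma2 <- sum((g - mu)^2 * px)
  gi <- matrix(g, Ng, Ng)
  gj <- t(gi)
  dmat <- gi - gj
  smat <- gi + gj

  pd <- tapply(as.vector(P), abs(as.vector(dmat)), sum)
  kd <- as.numeric(names(pd))
  ps <- tapply(as.vector(P), as.vector(smat), sum)
  ks <- as.numeric(names(ps))

  DA <- sum(kd * pd)
  HXY <- -sum(ifelse(P > 0, P * log2(P), 0))
  pxy <- px[row(P)] * px[col(P)]
  HXY1 <- -sum(ifelse(P > 0, P * log2(pxy), 0))
  HXY2 <- -sum(ifelse(pxy > 0, pxy * log2(pxy), 0))
  HX <- -sum(ifelse(px > 0, px * log2(px), 0))

  mcc <- 1
  if (Ng > 1) {
    py <- colSums(P)
    denom <- outer(px, py)
    denom[denom == 0] <- 1
    Q <- (P / denom) %*% t(P)
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(evq[2], 0))
  }

  c(
    Autocorrelation = sum(gi * gj * P),
    ClusterProminence = sum((smat - 2 * mu)^4 * P),
    ClusterShade = sum((smat - 2 * mu)^3 * P),
    ClusterTendency = sum((smat - 2 * mu)^2 * P),
    Contrast = sum(dmat^2 * P),
    Correlation = if (sigma2 > 0) (sum(gi * gj * P) - mu^2) / sigma2 else 1,
    DifferenceAverage = DA,
    DifferenceEntropy = -sum(ifelse(pd > 0, pd * log2(pd), 0)),
    DifferenceVariance = sum((kd - DA)^2 * pd),
    Id = sum(P / (1 + abs(dmat))),
    Idm = sum(P / (1 + dmat^2)),
    Idmn = sum(P / (1 + (dmat / Ng)^2)),
    Idn = sum(P / (1 + abs(dmat) / Ng)),
    Imc1 = if (max(HX, HX) > 0) (HXY - HXY1) / HX else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    InverseVariance = if (Ng > 1) sum((P / (dmat^2 + (dmat == 0)))[dmat != 0]) else 0,
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ifelse(ps > 0, ps * log2(ps), 0)),
    SumSquares = sum((gi - mu)^2 * P)
  )
}

glcmFeatures <- function(lev) {
  Lmax <- max(lev)
  dirs <- .directions13()
  acc <- NULL
  for (d in seq_len(nrow(dirs))) {
    pr <- .shiftPairs(lev, dirs[d, ])
    keep <- pr$a > 0L & pr$b > 0L
    a <- pr$a[keep]; b <- pr$b[keep]
    if (length(a) == 0L) next
    cnt <- matrix(tabulate((a - 1L) * Lmax + b, nbins = Lmax * Lmax),
                  Lmax, Lmax, byrow = TRUE)
    cnt <- cnt + t(cnt)  # symmetric co-occurrence
    f <- .glcmFromCounts(cnt)
    acc <- if (is.null(acc)) rbind(f) else rbind(acc, f)
  }
  if (is.null(acc)) {
    f <- rep(0, length(glcmFeatureNames()))
    names(f) <- glcmFeatureNames()
    return(f)
  }
  colMeans(acc)[glcmFeatureNames()]
}

## ---- size/run/dependence-style matrices -----------------------------------

# shared feature machinery for GLRLM / GLSZM / GLDM: a count matrix over
# (gray level, size-like index j), plus names for the size dimension.
.sizeMatrixFeatures <- function(counts, g, j, Np, flavor) {
  N <- sum(counts)
  p <- counts / N
  pg <- rowSums(p)
  pj <- colSums(p)
  gi <- matrix(g, length(g), length(j))
  jj <- matrix(j, length(g), length(j), byrow = TRUE)
  muG <- sum(gi * p)
  muJ <- sum(jj * p)
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  out <- c(
    GLN = sum(rowSums(counts)^2) / N,
    GLNN = sum(pg^2),
    GLV = sum((gi - muG)^2 * p),
    HGL = sum(gi^2 * p),
    LGL = sum(p / gi^2),
    SN = sum(colSums(counts)^2) / N,
    SNN = sum(pj^2),
    SV = sum((jj - muJ)^2 * p),
    SE = ent,
    SmallE = sum(p / jj^2),
    LargeE = sum(p * jj^2),
    SmallLow = sum(p / (gi^2 * jj^2)),
    SmallHigh = sum(p * gi^2 / jj^2),
    LargeLow = sum(p * jj^2 / gi^2),
    LargeHigh = sum(p * jj^2 * gi^2),
    Pct = N / Np
  )
  names(out) <- switch(flavor,
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LowGrayLevelRunEmphasis", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunVariance", "RunEntropy",
              "ShortRunEmphasis", "LongRunEmphasis",
              "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis",
              "RunPercentage"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
              "SizeZoneNonUniformityNormalized", "ZoneVariance", "ZoneEntropy",
              "SmallAreaEmphasis", "LargeAreaEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "ZonePercentage"),
    gldm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
             "GrayLevelVariance", "HighGrayLevelEmphasis",
             "LowGrayLevelEmphasis", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "DependenceVariance",
             "DependenceEntropy", "SmallDependenceEmphasis",
             "LargeDependenceEmphasis", "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis", "Pct")
  )
  out
}

# condense (value, size) observations into a count matrix over present levels
.countMatrix <- function(levelVec, sizeVec) {
  g <- sort(unique(levelVec))
  s <- seq_len(max(sizeVec))
  counts <- matrix(0, length(g), length(s))
  tab <- table(factor(levelVec, levels = g), factor(sizeVec, levels = s))
  counts[] <- as.numeric(tab)
  list(counts = counts, g = as.numeric(g), j = as.numeric(s))
}

glrlmFeatureNames <- function() c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)

glrlmFeatures <- function(lev) {
  Np <- sum(lev > 0L)
  runs <- .cpp_run_counts(as.integer(lev), dim(lev), .directions13())
  acc <- NULL
  for (d in sort(unique(runs[, 1]))) {
    sel <- runs[, 1] == d
    cm <- .countMatrix(runs[sel, 2], runs[sel, 3])
    f <- .sizeMatrixFeatures(cm$counts, cm$g, cm$j, Np, "glrlm")
    acc <- if (is.null(acc)) rbind(f) else rbind(acc, f)
  }
  colMeans(acc)[glrlmFeatureNames()]
}

glszmFeatureNames <- function() c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance"
)

glszmFeatures <- function(lev) {
  Np <- sum(lev > 0L)
  z <- .zoneSizes(lev)
  cm <- .countMatrix(z[, 1], z[, 2])
  f <- .sizeMatrixFeatures(cm$counts, cm$g, cm$j, Np, "glszm")
  f[glszmFeatureNames()]
}

gldmFeatureNames <- function() c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

# per-voxel neighbor statistics over the 26-neighborhood: for each in-mask
# voxel, the number of in-mask neighbors, the number of equal-level
# neighbors, and the sum of neighbor levels.
.neighborStats <- function(lev) {
  d <- dim(lev)
  dirs <- .directions13()
  nNb <- array(0, dim = d)
  nEq <- array(0, dim = d)
  sumNb <- array(0, dim = d)
  addShift <- function(off) {
    xr <- max(1, 1 - off[1]):min(d[1], d[1] - off[1])
    yr <- max(1, 1 - off[2]):min(d[2], d[2] - off[2])
    zr <- max(1, 1 - off[3]):min(d[3], d[3] - off[3])
    x2 <- xr + off[1]; y2 <- yr + off[2]; z2 <- zr + off[3]
    a <- lev[xr, yr, zr]; b <- lev[x2, y2, z2]
    ok <- (a > 0L) & (b > 0L)
    nNb[xr, yr, zr] <<- nNb[xr, yr, zr] + ok
    nEq[xr, yr, zr] <<- nEq[xr, yr, zr] + (ok & (a == b))
    sumNb[xr, yr, zr] <<- sumNb[xr, yr, zr] + ifelse(ok, b, 0)
  }
  for (k in seq_len(nrow(dirs))) {
    addShift(dirs[k, ])
    addShift(-dirs[k, ])
  }
  list(nNb = nNb, nEq = nEq, sumNb = sumNb)
}

gldmFeatures <- function(lev, alpha = 0) {
  ns <- .neighborStats(lev)
  inm <- lev > 0L
  # dependence = equal-level neighbors (alpha = 0) + the center voxel itself
  dep <- ns$nEq[inm] + 1
  cm <- .countMatrix(lev[inm], dep)
  f <- .sizeMatrixFeatures(cm$counts, cm$g, cm$j, sum(inm), "gldm")
  f[gldmFeatureNames()]
}

ngtdmFeatureNames <- function() c(
  "Busyness", "Coarseness", "Complexity", "Contrast", "Strength"
)

ngtdmFeatures <- function(lev) {
  ns <- .neighborStats(lev)
  inm <- lev > 0L & ns$nNb > 0
  gv <- lev[inm]
  A <- ns$sumNb[inm] / ns$nNb[inm]
  Nvp <- sum(inm)
  g <- sort(unique(gv))
  ni <- as.numeric(table(factor(gv, levels = g)))
  si <- as.numeric(tapply(abs(gv - A), factor(gv, levels = g), sum))
  si[is.na(si)] <- 0
  pi <- ni / Nvp
  Ngp <- length(g)

  iMat <- matrix(g, Ngp, Ngp)
  jMat <- t(iMat)
  piM <- matrix(pi, Ngp, Ngp)
  pjM <- t(piM)
  both <- piM > 0 & pjM > 0

  coarseDen <- sum(pi * si)
  coarseness <- if (coarseDen > 0) 1 / coarseDen else 1e6
  contrast <- if (Ngp > 1)
    sum((piM * pjM * (iMat - jMat)^2)[both]) / (Ngp * (Ngp - 1)) *
      sum(si) / Nvp else 0
  busyDen <- sum(abs(iMat * piM - jMat * pjM)[both])
  busyness <- if (Ngp > 1 && busyDen > 0) coarseDen / busyDen else 0
  siM <- matrix(si, Ngp, Ngp)
  sjM <- t(siM)
  complexity <- sum((abs(iMat - jMat) * (piM * siM + pjM * sjM) /
                       (piM + pjM))[both]) / Nvp
  strengthDen <- sum(si)
  strength <- if (strengthDen > 0)
    sum(((piM + pjM) * (iMat - jMat)^2)[both]) / strengthDen else 0

  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}
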