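test_that("resampling: fixed point, constants, and geometry oracle", {
  set.seed(2)
  d <- c(10, 10, 8)
  img <- array(rnorm(prod(d)), d)
  mask <- array(FALSE, d); mask[3:8, 3:8, 2:6] <- TRUE

  rs <- resampleImageMask(img, mask, c(1, 1, 1))
  expect_identical(rs$image, img)  # identity fast path at matching spacing

  rc <- resampleImageMask(array(7, d), mask, c(2, 2, 2))
  expect_equal(range(rc$image), c(7, 7))  # constants reproduced exactly

  # 2 mm ellipsoid -> 1 mm: ~8x the voxel count
  d2 <- c(24, 24, 24)
  m2 <- kineticrad:::.ellipsoidMask(d2, c(12, 12, 12), c(8, 7, 6))
  r2 <- resampleImageMask(array(rnorm(prod(d2)), d2), m2, c(2, 2, 2))
  expect_lt(abs(sum(r2$mask) / sum(m2) - 8) / 8, 0.05)

  # empty-after-resampling guard
  m1 <- array(FALSE, d); m1[5, 5, 5] <- TRUE
  expect_error(resampleImageMask(img, m1, c(0.4, 0.4, 0.4), c(1, 1, 1)),
               "segmentation error")
})

test_that("fixed-bin-width discretization follows the floor rule", {
  expect_identical(discretizeValues(c(0, 4.9, 5, 14.9), 5), c(1L, 1L, 2L, 3L))
  expect_identical(discretizeValues(rep(3.7, 10), 5), rep(1L, 10))
  v <- runif(50, 0, 40)
  expect_identical(discretizeValues(v, 5), discretizeValues(v + 100, 5))
  expect_equal(max(discretizeValues(v, 5)),
               floor((max(v) - min(v)) / 5) + 1)
})

test_that("wavelet bank: constants, impulse identity, shapes, oracle", {
  img <- array(4, c(8, 7, 6))
  b <- waveletBands(img)
  expect_identical(names(b), waveletBandNames())
  for (bn in names(b)) expect_identical(dim(b[[bn]]), dim(img))
  expect_equal(max(abs(b$LLL - 4 * 2^1.5)), 0, tolerance = 1e-10)
  for (bn in setdiff(names(b), "LLL"))
    expect_lt(max(abs(b[[bn]])), 1e-10)

  # impulse response equals the separable kernel (away from boundaries)
  lo <- kineticrad:::.COIF1_LO; hi <- kineticrad:::.COIF1_HI
  imp <- array(0, c(13, 13, 13)); imp[7, 7, 7] <- 1
  bi <- waveletBands(imp)
  expect_equal(sum(bi$LLH^2), sum(outer(outer(lo, lo), hi)^2), tolerance = 1e-10)

  # direct triple-loop convolution oracle on a random image
  set.seed(5)
  r <- array(rnorm(8 * 9 * 7), c(8, 9, 7))
  br <- waveletBands(r)
  expect_equal(br$HLL, oracle_conv3d(r, hi, lo, lo), tolerance = 1e-10)
  expect_equal(br$LHH, oracle_conv3d(r, lo, hi, hi), tolerance = 1e-10)
})

test_that("first-order features: moments, percentiles, degenerate input", {
  v <- c(1, 2, 2, 3, 5, 8, 13)
  f <- kineticrad:::firstOrderFeatures(v, binWidth = 2, voxelVolume = 2)
  expect_equal(unname(f["Mean"]), mean(v))
  expect_equal(unname(f["Variance"]), mean((v - mean(v))^2))
  expect_equal(unname(f["Energy"]), sum(v^2))
  expect_equal(unname(f["TotalEnergy"]), 2 * sum(v^2))
  expect_equal(unname(f["RootMeanSquared"]), sqrt(mean(v^2)))
  m2 <- mean((v - mean(v))^2); m3 <- mean((v - mean(v))^3)
  expect_equal(unname(f["Skewness"]), m3 / m2^1.5)
  expect_equal(unname(f["10Percentile"]), unname(quantile(v, 0.1)))

  fc <- kineticrad:::firstOrderFeatures(rep(4, 20), binWidth = 5)
  expect_equal(unname(fc["Skewness"]), 0)  # zero-variance convention
  expect_equal(unname(fc["Kurtosis"]), 0)
  expect_equal(unname(fc["Entropy"]), 0)
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("shape features: sphere symmetry and ellipsoid anisotropy", {
  d <- c(21, 21, 21)
  sphere <- kineticrad:::.ellipsoidMask(d, c(11, 11, 11), c(8, 8, 8))
  fs <- kineticrad:::shapeFeatures(sphere, c(1, 1, 1))
  expect_equal(unname(fs["Elongation"]), 1, tolerance = 0.05)
  expect_equal(unname(fs["Flatness"]), 1, tolerance = 0.05)
  expect_equal(unname(fs["VoxelVolume"]), sum(sphere))
  expect_equal(unname(fs["Maximum3DDiameter"]), 16, tolerance = 0.1)

  ell <- kineticrad:::.ellipsoidMask(d, c(11, 11, 11), c(9, 6, 3))
  fe <- kineticrad:::shapeFeatures(ell, c(1, 1, 1))
  expect_lt(fe["Elongation"], 0.8)
  expect_lt(fe["Flatness"], fe["Elongation"])
  # analytic ellipsoid axis ratio: Elongation ~ b/a = 6/9
  expect_equal(unname(fe["Elongation"]), 6 / 9, tolerance = 0.07)
})

test_that("texture matrices equal brute-force enumeration on small ROIs", {
  ns <- asNamespace("kineticrad")
  for (seed in 1:3) {
    lev <- oracle_random_roi(c(5, 5, 3), L = 4, seed = seed)
    dirs <- ns$.directions13()

    # GLSZM zones
    zi <- ns$.zoneSizes(lev)
    zo <- oracle_zones(lev)
    expect_equal(matrix(as.numeric(zi[order(zi[, 1], zi[, 2]), ]), ncol = 2),
                 matrix(as.numeric(zo[order(zo[, 1], zo[, 2]), ]), ncol = 2))

    # GLRLM runs, every direction
    runs <- ns$.cpp_run_counts(as.integer(lev), dim(lev), dirs)
    for (dd in 1:13) {
      ro <- oracle_runs(lev, dirs[dd, ])
      ri <- runs[runs[, 1] == dd, 2:3, drop = FALSE]
      expect_equal(
        matrix(as.numeric(ri[order(ri[, 1], ri[, 2]), ]), ncol = 2),
        matrix(as.numeric(ro[order(ro[, 1], ro[, 2]), ]), ncol = 2))
    }

    # GLDM dependence multiset
    dep_o <- oracle_dependence(lev)
    nsb <- ns$.neighborStats(lev)
    inm <- lev > 0
    expect_identical(sort(paste(lev[inm], nsb$nEq[inm] + 1)),
                     sort(paste(dep_o[, 1], dep_o[, 2])))

    # GLCM pair counts, every direction
    for (dd in 1:13) {
      pr <- ns$.shiftPairs(lev, dirs[dd, ])
      keep <- pr$a > 0 & pr$b > 0
      L <- max(lev)
      cnt <- matrix(tabulate((pr$a[keep] - 1L) * L + pr$b[keep], L * L),
                    L, L, byrow = TRUE)
      expect_equal(cnt + t(cnt), oracle_glcm_counts(lev, dirs[dd, ]))
    }

    # NGTDM stats
    st <- oracle_ngtdm_stats(lev)
    inb <- lev > 0 & nsb$nNb > 0
    expect_equal(sum(inb), st$nvp)
    A <- nsb$sumNb[inb] / nsb$nNb[inb]
    siImpl <- as.numeric(tapply(abs(lev[inb] - A),
                                factor(lev[inb], levels = st$g), sum))
    siImpl[is.na(siImpl)] <- 0
    expect_equal(siImpl, st$si)
  }
})

test_that("named texture features equal independent formula oracles", {
  ns <- asNamespace("kineticrad")
  lev <- oracle_random_roi(c(5, 5, 3), L = 4, seed = 7)
  np <- sum(lev > 0)
  dirs <- ns$.directions13()

  se <- mean(vapply(1:13, function(dd)
    oracle_glcm_sum_entropy(oracle_glcm_counts(lev, dirs[dd, ])), numeric(1)))
  expect_equal(unname(ns$glcmFeatures(lev)["SumEntropy"]), se)

  zo <- oracle_zones(lev)
  ofz <- oracle_size_features(zo, np)
  zf <- ns$glszmFeatures(lev)
  expect_equal(unname(zf["GrayLevelNonUniformityNormalized"]),
               ofz$GrayLevelNonUniformityNormalized)
  expect_equal(unname(zf["HighGrayLevelZoneEmphasis"]),
               ofz$HighGrayLevelZoneEmphasis)
  expect_equal(unname(zf["LowGrayLevelZoneEmphasis"]),
               ofz$LowGrayLevelZoneEmphasis)
  expect_equal(unname(zf["SmallAreaEmphasis"]), ofz$SmallAreaEmphasis)
  expect_equal(unname(zf["GrayLevelNonUniformity"]), ofz$GrayLevelNonUniformity)
  expect_equal(unname(zf["ZonePercentage"]), ofz$ZonePercentage)

  do <- oracle_dependence(lev)
  ofd <- oracle_size_features(do, np)
  gf <- ns$gldmFeatures(lev)
  expect_equal(unname(gf["LargeDependenceLowGrayLevelEmphasis"]),
               ofd$LargeDependenceLowGrayLevelEmphasis)
  expect_equal(unname(gf["LowGrayLevelEmphasis"]), ofd$LowGrayLevelZoneEmphasis)
  expect_equal(unname(gf["DependenceVariance"]), ofd$DependenceVariance)

  expect_equal(unname(ns$ngtdmFeatures(lev)["Busyness"]),
               oracle_ngtdm_busyness(lev))

  # GLRLM: direction-averaged short-run emphasis vs direct enumeration
  sreO <- mean(vapply(1:13, function(dd) {
    ro <- oracle_runs(lev, dirs[dd, ])
    mean(1 / ro[, 2]^2)
  }, numeric(1)))
  expect_equal(unname(ns$glrlmFeatures(lev)["ShortRunEmphasis"]), sreO)
})

test_that("degenerate single-gray-level ROI follows the stated conventions", {
  lev <- array(0L, c(5, 5, 3))
  lev[2:4, 2:4, 1:2] <- 1L
  ns <- asNamespace("kineticrad")
  expect_equal(unname(ns$glszmFeatures(lev)["GrayLevelNonUniformityNormalized"]), 1)
  expect_equal(unname(ns$ngtdmFeatures(lev)["Busyness"]), 0)
  expect_equal(unname(ns$glcmFeatures(lev)["Correlation"]), 1)
})

test_that("feature extraction yields the full named panel with invariances", {
  spec <- smallSpec()
  p <- generatePatient(spec, "HER2+", seed = 21)
  img <- sourceImages(p$series, p$mask)$MRORI
  f <- extractFeatures(img, maskArray(p$mask), c(1, 1, 1), extractionConfig())
  expect_length(f, 851)
  expect_false(anyDuplicated(names(f)) > 0)
  expect_true(all(is.finite(f)))

  # every published wavelet/texture feature name is a producible column
  for (nm in c("original_glcm_SumEntropy",
               "wavelet-LLH_glszm_GrayLevelNonUniformityNormalized",
               "wavelet-HHL_firstorder_Skewness",
               "wavelet-HHL_glszm_HighGrayLevelZoneEmphasis",
               "wavelet-LLL_ngtdm_Busyness",
               "original_shape_Elongation",
               "wavelet-LHL_glszm_SmallAreaEmphasis",
               "wavelet-HLL_gldm_LargeDependenceLowGrayLevelEmphasis",
               "wavelet-HLH_firstorder_TotalEnergy",
               "wavelet-LHL_gldm_LowGrayLevelEmphasis",
               "wavelet-HLH_gldm_LargeDependenceLowGrayLevelEmphasis",
               "wavelet-HLH_glszm_LowGrayLevelZoneEmphasis",
               "wavelet-LLL_gldm_DependenceVariance",
               "wavelet-LLL_glszm_SmallAreaEmphasis"))
    expect_true(nm %in% names(f), label = nm)

  # texture features invariant to a constant intensity shift
  f2 <- extractFeatures(img + 100, maskArray(p$mask), c(1, 1, 1),
                        extractionConfig())
  tex <- grep("original_(glcm|glrlm|glszm|ngtdm|gldm)_", names(f), value = TRUE)
  expect_equal(f[tex], f2[tex], tolerance = 1e-8)

  expect_error(extractFeatures(img, array(FALSE, dim(img)) , c(1, 1, 1)),
               "degenerate-ROI")
})

test_that("feature tables are rectangular, named, and tagged by source", {
  spec <- phantomSpec(nPerClass = c(1L, 1L, 1L), gridShape = c(16L, 16L, 16L),
                      lesionRadii = c(3.5, 4.5))
  co <- generateCohort(spec)
  tabs <- cohortFeatureTables(co, runConfig(phantom = spec))
  expect_named(tabs, c("TICWIR", "TICArea", "MRORI"))
  for (s in names(tabs)) {
    expect_equal(dim(tabs[[s]]), c(3, 851))
    expect_true(all(startsWith(names(tabs[[s]]), paste0(s, "_"))))
  }
  expect_true("TICArea_wavelet-LLH_glszm_GrayLevelNonUniformityNormalized"
              %in% names(tabs$TICArea))
})
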