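# Voxel-wise TIC parametric maps. Post-contrast signal is normalized by the
# pre-contrast signal; the wash-in rate uses the normalized peak within the
# first three post-contrast phases, and the area map is the trapezoidal
# integral of the normalized curve from injection (t = 0, s = 1) to the last
# phase, divided by the total acquisition time t_N.

.DEGENERATE_EPS <- 1e-6  # relative to the in-volume pre-contrast maximum

# normalized signal matrix (voxels x phases) + degenerate-voxel handling;
# degenerate voxels (pre <= eps * max(pre)) get s = 1 (flat curve) and are
# counted, so downstream maps are 0 there rather than NaN/Inf.
.normalizedSignal <- function(series) {
  pre <- as.vector(prePhase(series))
  floorv <- .DEGENERATE_EPS * max(pre)
  degen <- pre <= floorv
  safePre <- ifelse(degen, 1, pre)
  s <- vapply(postPhases(series),
              function(v) as.vector(v) / safePre,
              numeric(length(pre)))
  s[degen, ] <- 1
  list(s = s, degenerate = degen)
}

#' Wash-in rate (WIR) parametric map
#'
#' For each voxel the normalized peak `I_peak_norm = max(s_1, s_2, s_3)` is
#' found over the first three post-contrast phases (ties broken by the
#' earliest phase) and the map value is `(I_peak_norm - 1) / T_peak` in 1/s,
#' where `T_peak` is the acquisition time of the peak phase relative to
#' injection. Voxels that never exceed baseline within the first three
#' phases map to 0 (the value is floored at zero), and voxels with a
#' degenerate pre-contrast signal are zeroed and counted.
#'
#' @param series a [DCESeries-class].
#' @return a [ParametricMap-class] of kind `"WIR"`.
#' @export
computeWIRMap <- function(series) {
  ns <- .normalizedSignal(series)
  s3 <- ns$s[, 1:3, drop = FALSE]
  peak <- pmax(s3[, 1], s3[, 2], s3[, 3])
  idx <- max.col(s3, ties.method = "first")
  tPeak <- phaseTimes(series)[idx]
  wir <- pmax(peak - 1, 0) / tPeak
  wir[ns$degenerate] <- 0
  new("ParametricMap",
      map = array(wir, dim = dim(prePhase(series))), kind = "WIR",
      spacing = voxelSpacing(series), phaseTimes = phaseTimes(series),
      patientID = patientID(series), nDegenerate = sum(ns$degenerate))
}

#' Normalized area under the TIC parametric map
#'
#' For each voxel the trapezoidal rule integrates the normalized curve
#' through the points `(0, 1), (t_1, s_1), ..., (t_N, s_N)` and the result is
#' divided by `t_N`, making the map dimensionless (a flat, non-enhancing
#' curve gives exactly 1) and comparable across 4- and 5-phase protocols.
#' Degenerate pre-contrast voxels are zeroed and counted.
#'
#' @param series a [DCESeries-class].
#' @return a [ParametricMap-class] of kind `"Area"`.
#' @export
computeAreaMap <- function(series) {
  ns <- .normalizedSignal(series)
  tt <- c(0, phaseTimes(series))
  s <- cbind(1, ns$s)  # baseline point at injection
  np <- length(tt)
  # trapezoid weights: w_i = (t_{i+1} - t_{i-1}) / 2 with one-sided ends
  wts <- (c(diff(tt), 0) + c(0, diff(tt))) / 2
  area <- as.vector(s %*% wts) / tt[np]
  area[ns$degenerate] <- 0
  new("ParametricMap",
      map = array(area, dim = dim(prePhase(series))), kind = "Area",
      spacing = voxelSpacing(series), phaseTimes = phaseTimes(series),
      patientID = patientID(series), nDegenerate = sum(ns$degenerate))
}

#' Peak enhancement phase of the tumor
#'
#' Returns the post-contrast volume whose mean in-mask normalized intensity
#' is maximal (earliest phase on ties), the single-phase image a conventional
#' radiomics baseline is built from.
#'
#' @param series a [DCESeries-class].
#' @param mask a [TumorMask-class] on the series grid.
#' @return list with `volume` (raw post-contrast 3D array), `index`
#'   (1-based phase index) and `meanEnhancement` (per-phase in-mask means).
#' @export
peakEnhancementPhase <- function(series, mask) {
  stopifnot(identical(dim(maskArray(mask)), dim(prePhase(series))))
  ns <- .normalizedSignal(series)
  m <- as.vector(maskArray(mask))
  means <- colMeans(ns$s[m, , drop = FALSE])
  idx <- which.max(means)  # which.max takes the earliest on exact ties
  list(volume = postPhases(series)[[idx]], index = idx, meanEnhancement = means)
}
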