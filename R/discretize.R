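#' Fixed-bin-width gray-level discretization
#'
#' Maps in-mask intensities to integer gray levels with the min-anchored
#' fixed-bin-width rule `level(v) = floor((v - min) / binWidth) + 1`, so
#' levels start at 1 and the number of levels is
#' `floor((max - min) / binWidth) + 1`. Constant input maps to a single
#' level. The rule is invariant to adding a constant to all intensities.
#'
#' @param values numeric vector of in-mask intensities.
#' @param binWidth positive bin width in intensity units.
#' @return integer gray levels, same length as `values`.
#' @export
discretizeValues <- function(values, binWidth) {
  stopifnot(length(values) > 0, binWidth > 0)
  as.integer(floor((values - min(values)) / binWidth)) + 1L
}

# 3D integer level array with 0 outside the mask (texture-matrix input)
.levelArray <- function(image, mask, binWidth) {
  lev <- array(0L, dim = dim(image))
  lev[mask] <- discretizeValues(image[mask], binWidth)
  lev
}
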