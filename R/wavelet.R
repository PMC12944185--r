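# Undecimated single-level separable 3D wavelet filter bank (Coiflet-1,
# symmetric boundary handling). Each of the 8 bands has the shape of the
# input; the band label gives the filter applied per axis in (x, y, z)
# order, e.g. "LLH" = low-pass in x and y, high-pass in z.

# Coiflet-1 decomposition filters (low/high pass); sum(lo) = sqrt(2), so a
# constant image has LLL gain 2^(3/2) and exactly zero in every H band.
.COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
               0.3848648468648578, 0.8525720202116004,
               0.3378976624574818, -0.07273261951252645)
.COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
               -0.8525720202116004, 0.3848648468648578,
               0.07273261951252645, -0.015655728135791993)

#' Wavelet band names
#' @return the 8 band labels `"LLL"` ... `"HHH"` in canonical order.
#' @export
waveletBandNames <- function() {
  bands <- expand.grid(x = c("L", "H"), y = c("L", "H"), z = c("L", "H"),
                       stringsAsFactors = FALSE)
  apply(bands, 1, paste0, collapse = "")
}

#' Undecimated 3D wavelet decomposition
#'
#' Single-level stationary (undecimated) separable wavelet transform with
#' Coiflet-1 filters and symmetric (half-sample reflected) padding. Returns
#' the 8 band images `LLL ... HHH`, each with the input's shape; the label's
#' k-th letter is the filter applied along the k-th array axis.
#'
#' @param image 3D numeric array.
#' @return named list of 8 arrays.
#' @export
waveletBands <- function(image) {
  stopifnot(length(dim(image)) == 3L)
  filt <- list(L = .COIF1_LO, H = .COIF1_HI)
  out <- list()
  for (band in waveletBandNames()) {
    letters3 <- strsplit(band, "")[[1]]
    v <- image
    for (ax in 1:3) v <- .convAxis(v, filt[[letters3[ax]]], ax)
    out[[band]] <- v
  }
  out
}
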