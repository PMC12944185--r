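#' Radiomics extraction configuration
#'
#' @param targetSpacing isotropic resampling target, mm (default 1 mm^3).
#' @param binWidth fixed bin width for gray-level discretization, in the
#'   intensity units of the image the features are extracted from. The
#'   conventional value of 5 suits raw MR signal; parametric maps live on
#'   much smaller scales (wash-in rate around 0.01 1/s, normalized area
#'   around 1-3), where a bin width of 5 collapses the ROI to a single gray
#'   level — set a per-source width via [runConfig()] for those.
#' @param cropMargin voxels of context kept around the mask bounding box
#'   before filtering (wavelet support).
#'
#' @return an `ExtractionConfig` list.
#' @export
extractionConfig <- function(targetSpacing = c(1, 1, 1), binWidth = 5,
                             cropMargin = 5L) {
  stopifnot(binWidth > 0, all(targetSpacing > 0))
  structure(list(targetSpacing = targetSpacing, binWidth = binWidth,
                 cropMargin = as.integer(cropMargin)),
            class = "ExtractionConfig")
}

.cropToMask <- function(image, mask, margin) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  list(image = image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

.textureBundle <- function(image, mask, binWidth) {
  lev <- .levelArray(image, mask, binWidth)
  c(
    stats::setNames(glcmFeatures(lev),
                    paste0("glcm_", glcmFeatureNames())),
    stats::setNames(glrlmFeatures(lev),
                    paste0("glrlm_", glrlmFeatureNames())),
    stats::setNames(glszmFeatures(lev),
                    paste0("glszm_", glszmFeatureNames())),
    stats::setNames(ngtdmFeatures(lev),
                    paste0("ngtdm_", ngtdmFeatureNames())),
    stats::setNames(gldmFeatures(lev),
                    paste0("gldm_", gldmFeatureNames()))
  )
}

#' Extract the standardized radiomics feature panel
#'
#' Crops to the mask bounding box, resamples image and mask to the target
#' spacing, then extracts: 14 shape features from the mask, 18 first-order
#' and 79 texture features (GLCM 24, GLRLM 16, GLSZM 16, NGTDM 5, GLDM 14)
#' from the original image, and first-order plus texture features from each
#' of the 8 undecimated wavelet bands — 851 features in total, named
#' `<filter>_<class>_<name>` (e.g. `wavelet-LLH_glszm_GrayLevelNonUniformityNormalized`).
#'
#' @param image 3D numeric array.
#' @param mask 3D logical array on the same grid.
#' @param spacing voxel spacing of `image` (mm).
#' @param config an [extractionConfig()].
#'
#' @return named numeric vector of 851 features.
#' @export
extractFeatures <- function(image, mask, spacing = c(1, 1, 1),
                            config = extractionConfig()) {
  stopifnot(inherits(config, "ExtractionConfig"))
  if (sum(mask) < 2L) stop("degenerate-ROI error: mask has fewer than 2 voxels")
  cr <- .cropToMask(image, mask, config$cropMargin)
  rs <- resampleImageMask(cr$image, cr$mask, spacing, config$targetSpacing)
  vv <- prod(rs$spacing)

  out <- stats::setNames(shapeFeatures(rs$mask, rs$spacing),
                         paste0("original_shape_", shapeFeatureNames()))
  vals <- rs$image[rs$mask]
  tx0 <- .textureBundle(rs$image, rs$mask, config$binWidth)
  out <- c(out,
           stats::setNames(firstOrderFeatures(vals, config$binWidth, vv),
                           paste0("original_firstorder_", firstOrderFeatureNames())),
           stats::setNames(tx0, paste0("original_", names(tx0))))

  bands <- waveletBands(rs$image)
  for (bn in names(bands)) {
    pre <- paste0("wavelet-", bn, "_")
    bvals <- bands[[bn]][rs$mask]
    tx <- .textureBundle(bands[[bn]], rs$mask, config$binWidth)
    out <- c(out,
             stats::setNames(firstOrderFeatures(bvals, config$binWidth, vv),
                             paste0(pre, "firstorder_", firstOrderFeatureNames())),
             stats::setNames(tx, paste0(pre, names(tx))))
  }
  out
}

#' Build a patients-by-features table from extracted vectors
#'
#' @param featureList named list (by patient id) of equal-length named
#'   feature vectors, as returned by [extractFeatures()].
#' @param source tag prepended to every column name (e.g. `"TICWIR"`),
#'   recording which image the features came from.
#'
#' @return data.frame, rows = patients (rownames = ids), columns =
#'   `<source>_<feature>`; deterministic column order, no missing values.
#' @export
featureTable <- function(featureList, source) {
  stopifnot(length(featureList) > 0)
  nm <- names(featureList[[1]])
  for (f in featureList) stopifnot(identical(names(f), nm))
  m <- do.call(rbind, featureList)
  colnames(m) <- paste0(source, "_", nm)
  if (anyDuplicated(colnames(m))) stop("duplicate feature names")
  if (any(!is.finite(m))) stop("non-finite feature values")
  as.data.frame(m)
}
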