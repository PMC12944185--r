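#' @import methods
NULL

#' Molecular subtype labels
#'
#' Canonical ordering of the three treatment-oriented breast cancer molecular
#' subtypes used throughout the package: hormone-receptor positive /
#' HER2-negative, HER2-positive, and triple-negative.
#'
#' @export
subtypeLevels <- function() c("HR+/HER2-", "HER2+", "TNBC")

#' DCESeries: a registered multiphase DCE-MRI acquisition
#'
#' Holds one pre-contrast 3D volume, an ordered list of post-contrast 3D
#' volumes on the same grid, the acquisition time of each post-contrast phase
#' in seconds relative to contrast injection, and the voxel spacing in mm.
#' At least three post-contrast phases are required because the wash-in rate
#' searches for the normalized peak within the first three phases.
#'
#' @slot pre 3D numeric array, pre-contrast volume.
#' @slot post list of 3D numeric arrays, post-contrast volumes in time order.
#' @slot phaseTimes numeric, seconds post-injection, one per post volume.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot patientID character identifier.
#'
#' @export
setClass("DCESeries",
  representation(
    pre = "array",
    post = "list",
    phaseTimes = "numeric",
    spacing = "numeric",
    patientID = "character"
  )
)

setValidity("DCESeries", function(object) {
  msgs <- character()
  d <- dim(object@pre)
  if (length(d) != 3L) msgs <- c(msgs, "pre-contrast volume must be a 3D array")
  if (length(object@post) < 3L)
    msgs <- c(msgs, "protocol error: at least 3 post-contrast phases are required")
  for (v in object@post) {
    if (!identical(dim(v), d))
      msgs <- c(msgs, "grid error: all volumes must share the pre-contrast grid")
  }
  if (length(object@phaseTimes) != length(object@post))
    msgs <- c(msgs, "timing error: one phase time per post-contrast volume")
  if (any(object@phaseTimes <= 0) || any(diff(object@phaseTimes) <= 0))
    msgs <- c(msgs, "timing error: phase times must be strictly increasing and positive")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "voxel spacing must be three positive values (mm)")
  if (length(msgs)) msgs else TRUE
})

#' TumorMask: a binary region of interest on the series grid
#'
#' @slot mask 3D logical array.
#' @slot spacing numeric(3), voxel spacing in mm.
#'
#' @export
setClass("TumorMask",
  representation(mask = "array", spacing = "numeric")
)

setValidity("TumorMask", function(object) {
  msgs <- character()
  if (length(dim(object@mask)) != 3L) msgs <- c(msgs, "mask must be a 3D array")
  if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  if (!any(object@mask)) msgs <- c(msgs, "segmentation error: mask is empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "voxel spacing must be three positive values (mm)")
  if (length(msgs)) msgs else TRUE
})

#' ParametricMap: a voxel-wise kinetic parameter image
#'
#' A 3D image whose voxel values are a kinetic parameter derived from the
#' normalized time-intensity curve: either the wash-in rate (WIR, 1/s) or the
#' time-normalized trapezoidal area under the curve (Area, dimensionless).
#'
#' @slot map 3D numeric array of parameter values.
#' @slot kind "WIR" or "Area".
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot phaseTimes phase times (s) the map was computed from.
#' @slot patientID source patient identifier.
#' @slot nDegenerate number of voxels where the pre-contrast signal was at or
#'   below the degeneracy floor; those voxels are set to 0 rather than NaN.
#'
#' @export
setClass("ParametricMap",
  representation(
    map = "array",
    kind = "character",
    spacing = "numeric",
    phaseTimes = "numeric",
    patientID = "character",
    nDegenerate = "integer"
  )
)

setValidity("ParametricMap", function(object) {
  msgs <- character()
  if (length(dim(object@map)) != 3L) msgs <- c(msgs, "map must be a 3D array")
  if (!object@kind %in% c("WIR", "Area")) msgs <- c(msgs, "kind must be 'WIR' or 'Area'")
  if (any(!is.finite(object@map))) msgs <- c(msgs, "map contains non-finite values")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DCESeries-class constructor
#' @param pre,post,phaseTimes,spacing,patientID see slots.
#' @export
DCESeries <- function(pre, post, phaseTimes, spacing = c(1, 1, 1),
                      patientID = "patient") {
  new("DCESeries", pre = pre, post = post, phaseTimes = as.numeric(phaseTimes),
      spacing = as.numeric(spacing), patientID = patientID)
}

#' @describeIn TumorMask-class constructor; numeric input is coerced with > 0.
#' @param mask,spacing see slots.
#' @export
TumorMask <- function(mask, spacing = c(1, 1, 1)) {
  if (!is.logical(mask)) {
    mask <- array(as.vector(mask) > 0, dim = dim(mask))
  }
  new("TumorMask", mask = mask, spacing = as.numeric(spacing))
}
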