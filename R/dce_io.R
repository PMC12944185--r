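# NIfTI readers/writers and grid/timing validation. Inputs are assumed to be
# registered already; multiphase registration is an upstream, external step.

.SPACING_TOL <- 1e-4  # mm; masks must share the series grid to this tolerance

#' Load a registered DCE series from NIfTI files
#'
#' @param paths character vector of NIfTI files, one per phase (pre-contrast
#'   included), all on the same grid.
#' @param timing numeric, seconds post-injection for each post-contrast phase
#'   (in file order, excluding the pre-contrast file); alternatively the path
#'   of a JSON sidecar with a `phase_times_s` field.
#' @param preIndex which element of `paths` is the pre-contrast phase.
#' @param patientID identifier.
#'
#' @return a validated [DCESeries-class].
#' @export
loadSeries <- function(paths, timing, preIndex = 1L, patientID = "patient") {
  stopifnot(length(paths) >= 4L)
  if (is.character(timing) && length(timing) == 1L && file.exists(timing))
    timing <- jsonlite::read_json(timing, simplifyVector = TRUE)$phase_times_s
  vols <- lapply(paths, RNifti::readNifti)
  arrs <- lapply(vols, function(v) array(as.numeric(v), dim = dim(v)))
  sp <- .niftiSpacing(vols[[1]])
  d <- dim(arrs[[1]])
  for (i in seq_along(arrs)) {
    if (!identical(dim(arrs[[i]]), d))
      stop("grid error: phase ", i, " has shape ",
           paste(dim(arrs[[i]]), collapse = "x"), ", expected ",
           paste(d, collapse = "x"))
    spi <- .niftiSpacing(vols[[i]])
    if (any(abs(spi - sp) > .SPACING_TOL))
      stop("grid error: phase ", i, " voxel spacing differs from phase 1")
  }
  post <- arrs[-preIndex]
  if (length(post) < 3L)
    stop("protocol error: at least 3 post-contrast phases are required")
  if (length(timing) != length(post))
    stop("timing error: ", length(timing), " phase times for ",
         length(post), " post-contrast volumes")
  if (any(timing <= 0) || any(diff(timing) <= 0))
    stop("timing error: phase times must be strictly increasing and positive")
  DCESeries(arrs[[preIndex]], post, timing, sp, patientID)
}

#' Load a tumor mask and check it against a series grid
#'
#' Values greater than zero are coerced to foreground. A mask whose
#' foreground splits into several 26-connected components triggers a warning
#' (not an error).
#'
#' @param path NIfTI file.
#' @param series the [DCESeries-class] the mask belongs to.
#'
#' @return a [TumorMask-class].
#' @export
loadMask <- function(path, series) {
  v <- RNifti::readNifti(path)
  arr <- array(as.numeric(v) > 0, dim = dim(v))
  if (!identical(dim(arr), dim(prePhase(series))))
    stop("grid error: mask shape ", paste(dim(arr), collapse = "x"),
         " does not match series grid ",
         paste(dim(prePhase(series)), collapse = "x"))
  sp <- .niftiSpacing(v)
  if (any(abs(sp - voxelSpacing(series)) > .SPACING_TOL))
    stop("grid error: mask voxel spacing differs from the series")
  if (!any(arr)) stop("segmentation error: mask is empty")
  ncomp <- nrow(.zoneSizes(array(as.integer(arr), dim = dim(arr))))
  if (ncomp > 1L)
    warning("mask has ", ncomp, " connected foreground components")
  TumorMask(arr, voxelSpacing(series))
}

.niftiSpacing <- function(img) {
  p <- RNifti::pixdim(img)
  as.numeric(p[seq_len(min(3L, length(p)))])
}

.writeVolume <- function(arr, spacing, file) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Write a DCE series as one NIfTI file per phase
#'
#' Writes `<prefix>_pre.nii.gz`, `<prefix>_post1.nii.gz`, ... plus a JSON
#' sidecar `<prefix>_timing.json` holding `phase_times_s`.
#'
#' @param series a [DCESeries-class].
#' @param prefix output path prefix.
#' @return the written file paths, invisibly.
#' @export
writeSeries <- function(series, prefix) {
  sp <- voxelSpacing(series)
  files <- character()
  f <- paste0(prefix, "_pre.nii.gz")
  .writeVolume(prePhase(series), sp, f)
  files <- c(files, f)
  posts <- postPhases(series)
  for (i in seq_along(posts)) {
    f <- paste0(prefix, "_post", i, ".nii.gz")
    .writeVolume(posts[[i]], sp, f)
    files <- c(files, f)
  }
  sidecar <- paste0(prefix, "_timing.json")
  jsonlite::write_json(list(phase_times_s = phaseTimes(series)), sidecar,
                       auto_unbox = FALSE, digits = NA)
  invisible(c(files, sidecar))
}

#' @describeIn writeSeries write a [TumorMask-class] as NIfTI.
#' @param mask a [TumorMask-class].
#' @param file output file.
#' @export
writeMask <- function(mask, file) {
  .writeVolume(array(as.integer(maskArray(mask)), dim = dim(maskArray(mask))),
               voxelSpacing(mask), file)
}

#' @describeIn writeSeries write a [ParametricMap-class] as NIfTI with a JSON
#'   sidecar recording its kind and phase times.
#' @param map a [ParametricMap-class].
#' @export
writeMap <- function(map, file) {
  .writeVolume(mapArray(map), voxelSpacing(map), file)
  jsonlite::write_json(
    list(kind = mapKind(map), phase_times_s = phaseTimes(map),
         patient_id = patientID(map), n_degenerate = map@nDegenerate),
    sub("\\.nii(\\.gz)?$", ".json", file), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Load a subtype label table
#'
#' @param path CSV with columns `patient_id` and `subtype`.
#' @return data.frame with unique patient ids and subtypes restricted to
#'   [subtypeLevels()].
#' @export
loadLabels <- function(path) {
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "subtype") %in% names(lab)))
    stop("label table must have columns patient_id and subtype")
  if (anyDuplicated(lab$patient_id))
    stop("duplicate patient_id in label table")
  bad <- setdiff(unique(lab$subtype), subtypeLevels())
  if (length(bad))
    stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
  lab
}
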