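#' Accessors for imaging classes
#'
#' `prePhase`, `postPhases`, `phaseTimes`, `voxelSpacing`, `patientID`,
#' `maskArray`, `mapArray` and `mapKind` retrieve the corresponding slots of
#' [DCESeries-class], [TumorMask-class] and [ParametricMap-class] objects.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("prePhase", function(x) standardGeneric("prePhase"))
#' @rdname accessors
#' @export
setGeneric("postPhases", function(x) standardGeneric("postPhases"))
#' @rdname accessors
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("patientID", function(x) standardGeneric("patientID"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("mapArray", function(x) standardGeneric("mapArray"))
#' @rdname accessors
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname accessors
setMethod("prePhase", "DCESeries", function(x) x@pre)
#' @rdname accessors
setMethod("postPhases", "DCESeries", function(x) x@post)
#' @rdname accessors
setMethod("phaseTimes", "DCESeries", function(x) x@phaseTimes)
#' @rdname accessors
setMethod("voxelSpacing", "DCESeries", function(x) x@spacing)
#' @rdname accessors
setMethod("patientID", "DCESeries", function(x) x@patientID)
#' @rdname accessors
setMethod("voxelSpacing", "TumorMask", function(x) x@spacing)
#' @rdname accessors
setMethod("maskArray", "TumorMask", function(x) x@mask)
#' @rdname accessors
setMethod("mapArray", "ParametricMap", function(x) x@map)
#' @rdname accessors
setMethod("mapKind", "ParametricMap", function(x) x@kind)
#' @rdname accessors
setMethod("voxelSpacing", "ParametricMap", function(x) x@spacing)
#' @rdname accessors
setMethod("phaseTimes", "ParametricMap", function(x) x@phaseTimes)
#' @rdname accessors
setMethod("patientID", "ParametricMap", function(x) x@patientID)

setMethod("show", "DCESeries", function(object) {
  d <- dim(object@pre)
  cat("DCESeries '", object@patientID, "': ", paste(d, collapse = "x"),
      " voxels, ", length(object@post), " post-contrast phases at ",
      paste(object@phaseTimes, collapse = "/"), " s, spacing ",
      paste(object@spacing, collapse = "x"), " mm\n", sep = "")
})

setMethod("show", "TumorMask", function(object) {
  cat("TumorMask: ", sum(object@mask), " foreground voxels on a ",
      paste(dim(object@mask), collapse = "x"), " grid\n", sep = "")
})

setMethod("show", "ParametricMap", function(object) {
  v <- object@map
  cat("ParametricMap [", object@kind, "] '", object@patientID, "': ",
      paste(dim(v), collapse = "x"), " voxels, range ",
      signif(min(v), 4), "..", signif(max(v), 4),
      if (object@nDegenerate > 0) paste0(", ", object@nDegenerate, " degenerate voxels zeroed"),
      "\n", sep = "")
})
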