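#' Number of maps in a collection
#' @param x a \linkS4class{SpatialMapSet} or \linkS4class{RunSet}.
#' @return integer scalar.
#' @export
setGeneric("nMaps", function(x) standardGeneric("nMaps"))

#' Masked map values
#'
#' Matrix of per-voxel values (in-mask voxels x maps).
#' @param x a \linkS4class{SpatialMapSet} or \linkS4class{RunSet}.
#' @return numeric matrix.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Brain mask of an object
#' @param x an object carrying a 3-D logical mask.
#' @return logical 3-D array.
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' Map provenance table
#' @param x a \linkS4class{SpatialMapSet} or \linkS4class{RunSet}.
#' @return data.frame, one row per map.
#' @export
setGeneric("mapInfo", function(x) standardGeneric("mapInfo"))

#' Mixing time courses
#' @param x a \linkS4class{RunSet}.
#' @return numeric matrix, timepoints x maps.
#' @export
setGeneric("timeCourses", function(x) standardGeneric("timeCourses"))

#' Component-number settings
#' @param x a \linkS4class{ComponentRange}.
#' @return integer vector L = lower, lower + step, ..., upper.
#' @export
setGeneric("settings", function(x) standardGeneric("settings"))

#' @rdname nMaps
setMethod("nMaps", "SpatialMapSet", function(x) ncol(x@values))
#' @rdname nMaps
setMethod("nMaps", "RunSet", function(x) ncol(x@maps@values))

#' @rdname mapValues
setMethod("mapValues", "SpatialMapSet", function(x) x@values)
#' @rdname mapValues
setMethod("mapValues", "RunSet", function(x) x@maps@values)

#' @rdname brainMask
setMethod("brainMask", "SpatialMapSet", function(x) x@mask)
#' @rdname brainMask
setMethod("brainMask", "RunSet", function(x) x@maps@mask)
#' @rdname brainMask
setMethod("brainMask", "FmriVolume", function(x) x@mask)

#' @rdname mapInfo
setMethod("mapInfo", "SpatialMapSet", function(x) x@info)
#' @rdname mapInfo
setMethod("mapInfo", "RunSet", function(x) x@maps@info)

#' @rdname timeCourses
setMethod("timeCourses", "RunSet", function(x) x@timecourses)

#' @rdname settings
setMethod("settings", "ComponentRange", function(x) {
  seq.int(x@lower, x@upper, by = x@step)
})

setMethod("show", "FmriVolume", function(object) {
  d <- dim(object@data)
  cat("FmriVolume", object@subjectId,
    sprintf("[group %s]", object@groupLabel), "\n")
  cat("  grid:", paste(d[1:3], collapse = " x "),
    " timepoints:", d[4], "\n")
  cat("  in-mask voxels:", sum(object@mask), "\n")
})

setMethod("show", "SpatialMapSet", function(object) {
  cat("SpatialMapSet:", ncol(object@values), "map(s) over",
    nrow(object@values), "voxels\n")
  if (nrow(object@info)) {
    cat("  info columns:", paste(names(object@info), collapse = ", "), "\n")
  }
})

setMethod("show", "RunSet", function(object) {
  cat("RunSet subject", object@subjectId, "\n")
  cat(" ", object@nRuns, "restart(s) x", object@nComponents,
    "components =", nMaps(object), "maps\n")
  cat("  converged runs:", sum(object@converged), "/", object@nRuns, "\n")
})

setMethod("show", "ComponentRange", function(object) {
  l <- settings(object)
  cat("ComponentRange:", object@lower, "to", object@upper, "step",
    object@step, sprintf("(|L| = %d)\n", length(l)))
})
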