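#' @import methods
NULL

#' 4-D resting-state volume
#'
#' Container for one subject's preprocessed 4-D volume on a shared brain
#' mask. Voxel data are stored as an x-by-y-by-z-by-time array; the mask is a
#' logical 3-D array marking in-brain voxels. The affine is carried through
#' for NIfTI round trips but is not used numerically.
#'
#' @slot data numeric 4-D array (x, y, z, t).
#' @slot mask logical 3-D array, same spatial grid as \code{data}.
#' @slot affine 4x4 numeric matrix (voxel-to-world).
#' @slot subjectId character scalar.
#' @slot groupLabel character scalar (e.g. "patient"/"control").
#'
#' @export
setClass("FmriVolume",
  representation(
    data = "array",
    mask = "array",
    affine = "matrix",
    subjectId = "character",
    groupLabel = "character"
  )
)

setValidity("FmriVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4-D array")
  if (!identical(dim(object@mask), d[1:3])) {
    return("mask grid does not match data grid")
  }
  if (!is.logical(object@mask)) return("mask must be logical")
  if (sum(object@mask) == 0L) return("mask is empty")
  vox <- matrix(object@data, prod(d[1:3]), d[4])[as.vector(object@mask), ,
    drop = FALSE]
  if (any(!is.finite(vox))) return("non-finite values inside the mask")
  if (!identical(dim(object@affine), c(4L, 4L))) {
    return("affine must be a 4x4 matrix")
  }
  TRUE
})

#' Set of spatial maps over a shared mask
#'
#' A collection of per-voxel real-valued maps (ICs, group maps, cluster maps,
#' t-maps) restricted to a common brain mask. Values are stored as a
#' voxels-in-mask by maps matrix; \code{info} carries one provenance row per
#' map (subject, run, component index, map kind, ...).
#'
#' @slot values numeric matrix, masked voxels x maps.
#' @slot mask logical 3-D array; \code{sum(mask) == nrow(values)}.
#' @slot info data.frame with one row per map.
#'
#' @export
setClass("SpatialMapSet",
  representation(
    values = "matrix",
    mask = "array",
    info = "data.frame"
  )
)

setValidity("SpatialMapSet", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (sum(object@mask) != nrow(object@values)) {
    return("values rows must equal the number of in-mask voxels")
  }
  if (ncol(object@values) > 0 && any(!is.finite(object@values))) {
    return("non-finite map values")
  }
  if (nrow(object@info) != ncol(object@values)) {
    return("info must have one row per map")
  }
  TRUE
})

#' Pooled ICA decompositions of one subject at one component number
#'
#' All independent components and mixing time courses produced by repeated
#' ICA restarts of one subject at a single component-number setting. Maps are
#' z-scored over the mask and sign-aligned to nonnegative skewness;
#' the time courses are the matched mixing-matrix columns.
#'
#' @slot maps a \linkS4class{SpatialMapSet} holding nRuns * nComponents maps.
#' @slot timecourses numeric matrix, timepoints x (nRuns * nComponents).
#' @slot subjectId character scalar.
#' @slot nComponents integer, components per restart.
#' @slot nRuns integer, number of restarts.
#' @slot converged logical, one flag per restart.
#'
#' @export
setClass("RunSet",
  representation(
    maps = "SpatialMapSet",
    timecourses = "matrix",
    subjectId = "character",
    nComponents = "integer",
    nRuns = "integer",
    converged = "logical"
  )
)

setValidity("RunSet", function(object) {
  nm <- ncol(object@maps@values)
  if (nm != object@nComponents * object@nRuns) {
    return("map count must equal nComponents * nRuns")
  }
  if (ncol(object@timecourses) != nm) {
    return("one time course per map required")
  }
  if (length(object@converged) != object@nRuns) {
    return("one convergence flag per run required")
  }
  v <- object@maps@values
  if (nm > 0) {
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    if (max(abs(mu)) > 1e-6 || max(abs(sdv - 1)) > 1e-5) {
      return("maps must be z-scored over the mask")
    }
  }
  TRUE
})

#' Component-number range
#'
#' The set L of component numbers at which per-subject ICA is run, defined by
#' lower and upper bounds and a step.
#'
#' @slot lower integer lower bound.
#' @slot upper integer upper bound.
#' @slot step integer step size.
#'
#' @export
setClass("ComponentRange",
  representation(lower = "integer", upper = "integer", step = "integer")
)

setValidity("ComponentRange", function(object) {
  if (object@lower > object@upper) return("lower must be <= upper")
  if (object@step < 1L) return("step must be >= 1")
  if (object@lower < 1L) return("lower must be >= 1")
  TRUE
})
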