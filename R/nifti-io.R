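#' Write a volume to NIfTI-1
#'
#' @param vol a \linkS4class{FmriVolume}.
#' @param file output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeFmriVolume <- function(vol, file) {
  RNifti::writeNifti(RNifti::asNifti(vol@data), file)
  invisible(file)
}

#' Read a 4-D NIfTI volume
#'
#' @param file NIfTI path.
#' @param mask logical 3-D array, or path to a mask NIfTI; if NULL, every
#'   voxel with nonzero temporal variance is kept.
#' @param subjectId,groupLabel identifiers to attach.
#' @return a \linkS4class{FmriVolume}.
#' @export
readFmriVolume <- function(file, mask = NULL, subjectId = file,
                           groupLabel = "unknown") {
  img <- RNifti::readNifti(file)
  dat <- array(as.numeric(img), dim = dim(img))
  stopIfNot(length(dim(dat)) == 4, "expected a 4-D NIfTI volume")
  if (is.character(mask)) {
    m <- RNifti::readNifti(mask)
    mask <- array(as.numeric(m) != 0, dim = dim(m)[1:3])
  }
  if (is.null(mask)) {
    v <- matrix(dat, prod(dim(dat)[1:3]), dim(dat)[4])
    mask <- array(matrixStatsRowVar(v) > 0, dim = dim(dat)[1:3])
  }
  methods::new("FmriVolume", data = dat, mask = mask, affine = diag(4),
    subjectId = subjectId, groupLabel = groupLabel)
}

matrixStatsRowVar <- function(x) {
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (ncol(x) - 1)
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI per subject, a shared mask NIfTI, a TSV manifest
#' (subject_id, group, age, sex, file) and a ground-truth JSON.
#'
#' @param cohort result of \code{\link{synthesizeCohort}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort$volumes, function(v) {
    f <- file.path(dir, paste0(v@subjectId, ".nii.gz"))
    writeFmriVolume(v, f)
    f
  }, character(1))
  RNifti::writeNifti(RNifti::asNifti(cohort$mask * 1),
    file.path(dir, "mask.nii.gz"))
  manifest <- data.frame(
    subject_id = vapply(cohort$volumes, function(v) v@subjectId,
      character(1)),
    group = cohort$labels, age = cohort$age, sex = cohort$sex,
    file = basename(files))
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", row.names = FALSE,
    quote = FALSE)
  truth <- cohort$truth
  truthJson <- list(
    labels = truth$labels,
    sources = lapply(truth$sourceSpecs$control, function(s) {
      list(sourceId = s$sourceId, center = s$center, radius = s$radius,
        amplitude = s$amplitude)
    }),
    groupAmplitudeDelta = truth$spec$groupAmplitudeDelta,
    lagCoefficients = list(
      control = as.vector(truth$graphs$control$lagCoefficients),
      patient = as.vector(truth$graphs$patient$lagCoefficients)),
    seed = truth$spec$seed)
  jsonlite::write_json(truthJson, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifestPath)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory containing manifest.tsv and mask.nii.gz.
#' @return list with \code{volumes}, \code{labels}, \code{age}, \code{sex},
#'   \code{mask} (no truth bundle: that stays with the generator).
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  m <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  mask <- array(as.numeric(m) != 0, dim = dim(m)[1:3])
  vols <- lapply(seq_len(nrow(manifest)), function(i) {
    readFmriVolume(file.path(dir, manifest$file[i]), mask = mask,
      subjectId = manifest$subject_id[i], groupLabel = manifest$group[i])
  })
  list(volumes = vols, labels = manifest$group, age = manifest$age,
    sex = manifest$sex, mask = mask)
}

#' Write a map set as one 4-D NIfTI (map axis last)
#'
#' @param maps a \linkS4class{SpatialMapSet}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeMapSet <- function(maps, file) {
  grid <- dim(brainMask(maps))
  vals <- mapValues(maps)
  arr <- array(0, dim = c(grid, ncol(vals)))
  for (k in seq_len(ncol(vals))) {
    arr[, , , k] <- unmaskMap(vals[, k], brainMask(maps))
  }
  RNifti::writeNifti(RNifti::asNifti(arr), file)
  invisible(file)
}
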