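#' Construct a multiparametric imaging study for one subject
#'
#' Bundles the six co-registered channel volumes (CE-T1WI, T2WI, FLAIR, ADC,
#' rCBV, FDOPA-PET SUV) with the whole-brain and tumor-ROI masks, the IDH
#' genotype label and the subject's age. All volumes must share one voxel
#' grid; the tumor mask (the FLAIR-hyperintensity ROI) must be non-empty and
#' contained in the brain mask.
#'
#' @param subject_id character scalar.
#' @param channels named list of six 3-D numeric arrays, names and order as
#'   [gliosom_channels()].
#' @param brain_mask,tumor_mask 3-D logical arrays on the same grid.
#' @param genotype `"wildtype"` or `"mutant"`.
#' @param age age in years.
#' @return An object of class `gliosom_study`.
#' @export
new_study <- function(subject_id, channels, brain_mask, tumor_mask, genotype, age) {
  study <- structure(
    list(subject_id = as.character(subject_id),
         channels = channels,
         brain_mask = brain_mask,
         tumor_mask = tumor_mask,
         genotype = match.arg(genotype, c("wildtype", "mutant")),
         age = as.numeric(age)),
    class = "gliosom_study")
  validate_study(study)
  study
}

#' Validate a `gliosom_study`
#'
#' @param study object to check.
#' @return `study`, invisibly, or an error describing the violated invariant.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "gliosom_study"))
  if (!identical(names(study$channels), GLIOSOM_CHANNELS))
    stop("channels must be named ", paste(GLIOSOM_CHANNELS, collapse = ", "),
         " in that order")
  dims <- dim(study$channels[[1L]])
  if (length(dims) != 3L) stop("channel volumes must be 3-D arrays")
  for (nm in GLIOSOM_CHANNELS) {
    if (!identical(dim(study$channels[[nm]]), dims))
      stop("channel '", nm, "' is not on the common voxel grid")
  }
  for (m in c("brain_mask", "tumor_mask")) {
    if (!identical(dim(study[[m]]), dims)) stop(m, " is not on the common voxel grid")
    if (!is.logical(study[[m]])) stop(m, " must be logical (binary)")
  }
  if (!any(study$tumor_mask)) stop("tumor mask is empty")
  if (any(study$tumor_mask & !study$brain_mask))
    stop("tumor mask is not contained in the brain mask")
  invisible(study)
}

#' @export
print.gliosom_study <- function(x, ...) {
  cat(sprintf("<gliosom_study> %s  grid %s  genotype %s  age %.1f\n",
              x$subject_id, paste(dim(x$brain_mask), collapse = "x"),
              x$genotype, x$age))
  cat(sprintf("  brain voxels: %d  tumor voxels: %d\n",
              sum(x$brain_mask), sum(x$tumor_mask)))
  invisible(x)
}
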