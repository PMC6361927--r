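# NIfTI and tabular I/O. All volumes live in an axis-aligned AC-PC world
# frame; oblique/rotated grids are rejected (registration is out of scope).

gridFromAffine <- function(aff, shape) {
  R <- aff[1:3, 1:3]
  offdiag <- R; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(R))) || any(diag(R) <= 0)) {
    stop("NIfTI affine is not axis-aligned with positive spacings ",
         "(rotation/shear/flip unsupported); affine was:\n",
         paste(apply(round(aff, 4), 1L, paste, collapse = " "),
               collapse = "\n"), call. = FALSE)
  }
  VoxelGrid(shape, spacing = diag(R), origin = aff[1:3, 4])
}

gridToAffine <- function(grid) {
  aff <- diag(c(grid@spacing, 1))
  aff[1:3, 4] <- grid@origin
  aff
}

#' Read a volume from a NIfTI-1 file
#'
#' The affine must be axis-aligned (diagonal, positive spacings); spacing and
#' origin are taken from it. `kind = "mask"` binarizes (any nonzero value
#' becomes 1); `kind = "label"` requires integer-valued data.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind one of `"intensity"`, `"label"`, `"mask"`.
#' @param labelMap named integer vector for `kind = "label"`; defaults to
#'   `label<code>` names for the codes present.
#' @return An [IntensityVolume-class], [LabelVolume-class] or
#'   [ROIMask-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, kind = c("intensity", "label", "mask"),
                       labelMap = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stop("expected a 3D volume, got ",
                             length(dm), "D", call. = FALSE)
  grid <- gridFromAffine(structure(RNifti::xform(img), dim = c(4L, 4L)), dm)
  data <- as.array(img)
  attributes(data) <- list(dim = dm)
  switch(kind,
    intensity = IntensityVolume(data, grid),
    mask = ROIMask(data != 0, grid),
    label = {
      if (max(abs(data - round(data))) > 1e-6)
        stop("label volume contains non-integer values", call. = FALSE)
      data <- array(as.integer(round(data)), dm)
      if (is.null(labelMap)) {
        codes <- sort(setdiff(unique(as.vector(data)), 0L))
        labelMap <- structure(codes, names = paste0("label", codes))
      }
      LabelVolume(data, grid, labelMap)
    })
}

#' Write a volume to a NIfTI-1 file
#'
#' Masks and label volumes are stored with an integer datatype (lossless);
#' the affine encodes spacing and origin.
#'
#' @param vol an [IntensityVolume-class], [LabelVolume-class] or
#'   [ROIMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  data <- vol@data
  if (is(vol, "ROIMask") || is(vol, "LabelVolume"))
    storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol@grid@spacing
  aff <- gridToAffine(vol@grid)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a cohort volumetry table
#'
#' Reads a CSV with one row per (subject, hemisphere) carrying manual and
#' multi-atlas Vim volumes (mm^3, with thalamus-normalized percentages) and
#' the motor-cluster (VLV) volume (cm^3, with percentage). Missing cells are
#' empty strings in the CSV and become NA. The package ships a transcription
#' of the study cohort as `system.file("extdata", "table1.csv",
#' package = "vimloc")`.
#'
#' @param path CSV path (UTF-8, header row).
#' @return A [CohortTable-class].
#' @examples
#' tab <- loadCohortTable(system.file("extdata", "table1.csv",
#'                                    package = "vimloc"))
#' tab
#' @export
loadCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      hemisphere = "character"))
  missing_cols <- setdiff(cohortColumns, names(d))
  if (length(missing_cols))
    stop("cohort table misses columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in setdiff(cohortColumns, c("subject_id", "hemisphere")))
    d[[col]] <- as.numeric(d[[col]])
  new("CohortTable", data = d[cohortColumns])
}

#' Read / write a landmark set as JSON
#'
#' The JSON layout is
#' `{"AC":[x,y,z], "PC":[x,y,z], "thalamus_height_mm":h,
#'   "wall_x_mm":{"left":w, "right":w}}`.
#'
#' @param path JSON file path.
#' @return [readLandmarks()] returns a [LandmarkSet-class];
#'   [writeLandmarks()] returns `path` invisibly.
#' @export
readLandmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  LandmarkSet(ac = j$AC, pc = j$PC,
              thalamusHeightMm = j$thalamus_height_mm,
              wallXMm = c(left = j$wall_x_mm$left,
                          right = j$wall_x_mm$right))
}

#' @rdname readLandmarks
#' @param landmarks a [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
  jsonlite::write_json(
    list(AC = landmarks@ac, PC = landmarks@pc,
         thalamus_height_mm = landmarks@thalamusHeightMm,
         wall_x_mm = list(left = landmarks@wallXMm[["left"]],
                          right = landmarks@wallXMm[["right"]])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
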