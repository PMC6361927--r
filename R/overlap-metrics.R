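# Volumes, normalized volumes, Dice overlap, and cohort volumetry summaries.

#' Volume of a mask in cubic millimetres
#'
#' @param mask an [ROIMask-class].
#' @return `voxel count * prod(spacing)` in mm^3.
#' @export
volumeMm3 <- function(mask) voxelCount(mask) * prod(mask@grid@spacing)

#' Thalamus-normalized volume
#'
#' A structure's volume expressed as a percentage of the whole-thalamus
#' volume, making sizes comparable across hemispheres and subjects.
#'
#' @param mask an [ROIMask-class].
#' @param thalamus a nonempty [ROIMask-class] on the same grid.
#' @return Percentage in `[0, 100]` (for `mask` inside the thalamus).
#' @export
normalizedVolumePct <- function(mask, thalamus) {
  stopIfGridMismatch(mask, thalamus)
  vt <- volumeMm3(thalamus)
  if (vt == 0) stop("thalamus mask is empty", call. = FALSE)
  100 * volumeMm3(mask) / vt
}

#' Dice overlap coefficient
#'
#' `2 |A ^ B| / (|A| + |B|)` in voxel counts. Undefined (an error) when both
#' masks are empty.
#'
#' @param a,b [ROIMask-class] objects on the same grid.
#' @return A number in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  stopIfGridMismatch(a, b)
  denom <- voxelCount(a) + voxelCount(b)
  if (denom == 0L)
    stop("Dice is undefined for two empty masks", call. = FALSE)
  2 * sum(a@data & b@data) / denom
}

#' Overlap report for a pair of masks
#'
#' @param a,b [ROIMask-class] objects on the same grid.
#' @return An [OverlapReport-class] with Dice and mm^3 volumes.
#' @export
overlapReport <- function(a, b) {
  vox <- prod(a@grid@spacing)
  new("OverlapReport", dice = diceCoefficient(a, b),
      volAMm3 = volumeMm3(a), volBMm3 = volumeMm3(b),
      intersectionMm3 = sum(a@data & b@data) * vox)
}

#' Mean VLV-to-Vim size ratio of a cohort
#'
#' Ratio of the mean normalized VLV percentage to the mean normalized manual
#' Vim percentage over the rows that carry a manual delineation. The
#' normalized-percent route (rather than raw mm^3/cm^3) is used because
#' normalization is what makes the two structures comparable across
#' subjects; the rounded ratio is reported alongside.
#'
#' @param table a [CohortTable-class] with at least one row carrying both
#'   `vim_manual_pct` and `vlv_pct`.
#' @return `list(mean_ratio, rounded)`.
#' @export
vlvVimRatioSummary <- function(table) {
  d <- cohortData(table)
  keep <- !is.na(d$vim_manual_pct) & !is.na(d$vlv_pct)
  if (!any(keep))
    stop("no rows with both a manual Vim and a VLV percentage",
         call. = FALSE)
  r <- mean(d$vlv_pct[keep]) / mean(d$vim_manual_pct[keep])
  list(mean_ratio = r, rounded = round(r))
}

#' Cohort volumetry report
#'
#' Per-case volumes plus range/mean/sd summaries per column. The sd is the
#' sample standard deviation (n - 1). Accepts either a ready
#' [CohortTable-class] or a list of per-case masks (see
#' [cohortTableFromMasks()]).
#'
#' @param cases a [CohortTable-class], or a list of per-case mask sets for
#'   [cohortTableFromMasks()].
#' @return `list(per_case = data.frame, summary = data.frame)`; the summary
#'   has one row per statistic (min, max, mean, sd) and one column per
#'   numeric volumetry column.
#' @seealso [writeCohortReport()]
#' @export
cohortReport <- function(cases) {
  table <- if (is(cases, "CohortTable")) cases else cohortTableFromMasks(cases)
  d <- cohortData(table)
  numcols <- setdiff(cohortColumns, c("subject_id", "hemisphere"))
  stat <- function(f) vapply(numcols, function(cl)
    if (all(is.na(d[[cl]]))) NA_real_ else f(d[[cl]], na.rm = TRUE),
    numeric(1L))
  summary <- rbind(min = stat(min), max = stat(max), mean = stat(mean),
                   sd = stat(stats::sd))
  list(per_case = d, summary = as.data.frame(summary))
}

#' Build a cohort table from per-case masks
#'
#' Each case is a list with `subject_id`, `hemisphere`, a `thalamus`
#' [ROIMask-class], and optionally `vim_manual`, `vim_multiatlas` and `vlv`
#' masks (all on the subject's grid). Vim volumes are reported in mm^3, VLV
#' in cm^3, and all normalized percentages relative to the thalamus.
#'
#' @param cases list of per-case mask sets.
#' @return A [CohortTable-class].
#' @export
cohortTableFromMasks <- function(cases) {
  rows <- lapply(cases, function(cs) {
    thal <- cs$thalamus
    for (m in c("vim_manual", "vim_multiatlas", "vlv"))
      if (!is.null(cs[[m]])) stopIfGridMismatch(cs[[m]], thal)
    vol <- function(m) if (is.null(cs[[m]])) NA_real_ else volumeMm3(cs[[m]])
    pct <- function(m) if (is.null(cs[[m]])) NA_real_ else
      normalizedVolumePct(cs[[m]], thal)
    data.frame(subject_id = cs$subject_id, hemisphere = cs$hemisphere,
               vim_manual_mm3 = vol("vim_manual"),
               vim_manual_pct = pct("vim_manual"),
               vim_multiatlas_mm3 = vol("vim_multiatlas"),
               vim_multiatlas_pct = pct("vim_multiatlas"),
               vlv_cm3 = vol("vlv") / 1000,
               vlv_pct = pct("vlv"))
  })
  new("CohortTable", data = do.call(rbind, rows))
}

#' Write a cohort report as CSV
#'
#' Writes the per-case rows followed by min/max/mean/sd summary rows; an
#' empty cohort yields a header-only CSV.
#'
#' @param cases as in [cohortReport()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortReport <- function(cases, path) {
  rep <- cohortReport(cases)
  d <- rep$per_case
  if (nrow(d)) {
    s <- rep$summary
    srows <- data.frame(subject_id = paste0("(", rownames(s), ")"),
                        hemisphere = "", s, check.names = FALSE)
    d <- rbind(d, srows)
  }
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
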