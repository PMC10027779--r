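#' Construct a tumor growth curve
#'
#' A growth curve is the median tumor volume of one treatment group over
#' the course of the study, together with the staging volume (the volume at
#' which dosing started, ~200 mm3 in typical PDX protocols) against which
#' regression is measured.
#'
#' @param timepoints strictly increasing numeric vector of study days.
#' @param volumes numeric vector of median tumor volumes (mm3), same length
#'   as `timepoints`, all non-negative.
#' @param staging_volume positive staging volume (mm3). Default 200.
#' @return an object of class `pdx_growth_curve`.
#' @export
#' @examples
#' gc <- growth_curve(c(0, 7, 14, 21), c(200, 180, 130, 120))
#' label_response(gc)
growth_curve <- function(timepoints, volumes, staging_volume = 200) {
  if (length(timepoints) == 0L || length(volumes) == 0L)
    abort_validation("growth curve must have at least one timepoint")
  if (length(timepoints) != length(volumes))
    abort_validation("`timepoints` and `volumes` must have the same length")
  if (any(!is.finite(volumes)) || any(volumes < 0))
    abort_validation("`volumes` must be finite and non-negative")
  if (any(diff(timepoints) <= 0))
    abort_validation("`timepoints` must be strictly increasing")
  check_positive(staging_volume, "staging_volume")
  structure(list(timepoints = as.numeric(timepoints),
                 volumes = as.numeric(volumes),
                 staging_volume = as.numeric(staging_volume)),
            class = "pdx_growth_curve")
}

#' Binary modified-RECIST response label for a treatment group
#'
#' A group is a responder (label 1) if its median tumor volume regressed by
#' at least `regression_fraction` (default 30%) below the staging volume
#' for at least `min_consecutive` (default 2) consecutive timepoints at any
#' point during the study; otherwise it is a non-responder (label 0).
#' The boundary is inclusive: a volume exactly equal to
#' `(1 - regression_fraction) * staging_volume` counts as regression.
#'
#' @param curve a [growth_curve()].
#' @param regression_fraction fraction in (0, 1); default 0.30.
#' @param min_consecutive minimum length of the qualifying run; default 2.
#' @return integer 0 or 1.
#' @export
label_response <- function(curve, regression_fraction = 0.30,
                           min_consecutive = 2L) {
  if (!inherits(curve, "pdx_growth_curve"))
    curve <- growth_curve(curve$timepoints, curve$volumes, curve$staging_volume)
  if (regression_fraction <= 0 || regression_fraction >= 1)
    abort_validation("`regression_fraction` must be strictly between 0 and 1")
  min_consecutive <- check_count(min_consecutive, "min_consecutive")
  threshold <- (1 - regression_fraction) * curve$staging_volume
  below <- curve$volumes <= threshold
  runs <- rle(below)
  hit <- any(runs$values & runs$lengths >= min_consecutive)
  as.integer(hit)
}

#' Label every treatment group in a cohort manifest
#'
#' Applies [label_response()] to the tumor-volume timepoint columns
#' (`t0`, `t1`, ...) of a manifest and appends a `response` column.
#'
#' @param manifest data.frame with one row per treatment group and volume
#'   columns named `t0 ... tK`.
#' @param staging_volume staging volume shared by all groups (mm3).
#' @param regression_fraction,min_consecutive passed to [label_response()].
#' @return the manifest with an integer `response` column.
#' @export
label_manifest <- function(manifest, staging_volume = 200,
                           regression_fraction = 0.30, min_consecutive = 2L) {
  tcols <- grep("^t[0-9]+$", names(manifest), value = TRUE)
  if (length(tcols) == 0L)
    abort_validation("manifest has no timepoint columns (t0, t1, ...)")
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  days <- as.integer(sub("^t", "", tcols))
  manifest$response <- vapply(seq_len(nrow(manifest)), function(i) {
    vols <- as.numeric(manifest[i, tcols])
    keep <- !is.na(vols)
    label_response(growth_curve(days[keep], vols[keep], staging_volume),
                   regression_fraction, min_consecutive)
  }, integer(1))
  manifest
}
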