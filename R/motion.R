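## Rigid-body motion summaries and motion regression.
##
## The displacement statistics follow the printed formulas literally:
## translations (mm) and rotations (deg) are summed in quadrature without
## unit conversion. An optional deg->mm conversion on a 50 mm sphere is
## available but off by default.

#' Rigid-body motion trace
#'
#' @param params T x 6 data.frame or matrix with columns TraX, TraY, TraZ
#'   (mm) and RotX, RotY, RotZ (degrees).
#' @param tr repetition time, seconds.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(params, tr = 1) {
  params <- as.data.frame(params)
  expected <- c("TraX", "TraY", "TraZ", "RotX", "RotY", "RotZ")
  if (ncol(params) != 6L)
    stop_validation("motion trace needs exactly 6 columns")
  if (!all(expected %in% names(params))) names(params) <- expected
  params <- params[, expected]
  if (nrow(params) < 2L) stop_validation("motion trace needs T >= 2")
  if (!all(vapply(params, function(c) all(is.finite(c)), logical(1))))
    stop_validation("motion trace contains non-finite values")
  structure(list(params = params, tr = tr), class = "motion_trace")
}

#' Read a 6-column realignment parameter table
#'
#' @param path TSV path (realignment-parameter convention, 6 columns).
#' @param tr repetition time, seconds.
#' @return a [motion_trace()].
#' @export
read_motion <- function(path, tr = 1) {
  motion_trace(read_tsv(path), tr = tr)
}

#' @rdname read_motion
#' @param trace a [motion_trace()].
#' @export
write_motion <- function(trace, path) {
  write_tsv(trace$params, path)
  invisible(path)
}

rot_scaled <- function(trace, rot_to_mm) {
  p <- as.matrix(trace$params)
  if (isTRUE(rot_to_mm))
    p[, 4:6] <- p[, 4:6] * pi / 180 * 50   # arc length on a 50 mm sphere
  p
}

#' Mean displacement (delta)
#'
#' Mean over time of the root-sum-of-squares of the six motion parameters.
#'
#' @param trace a [motion_trace()].
#' @param rot_to_mm convert rotations from degrees to mm of arc on a 50 mm
#'   sphere before pooling (off by default: the formula mixes units as
#'   printed).
#' @return scalar.
#' @export
mean_displacement <- function(trace, rot_to_mm = FALSE) {
  p <- rot_scaled(trace, rot_to_mm)
  mean(sqrt(rowSums(p^2)))
}

#' Displacement speed (sigma)
#'
#' Mean over the T-1 successive volume-to-volume changes of the
#' root-sum-of-squares of the six per-TR parameter differences.
#'
#' @inheritParams mean_displacement
#' @return scalar.
#' @export
displacement_speed <- function(trace, rot_to_mm = FALSE) {
  p <- rot_scaled(trace, rot_to_mm)
  d <- diff(p)
  mean(sqrt(rowSums(d^2)))
}

#' Regress motion parameters out of a parcellated series
#'
#' Per region, returns the residuals of a least-squares fit on an intercept
#' plus the six motion columns; residuals are orthogonal to every motion
#' column. A rank-deficient design (e.g. an all-zero trace) is handled by the
#' pivoted QR, so zero motion simply demeans the series.
#'
#' @param series a [parcellated_series()].
#' @param trace a [motion_trace()] with matching T.
#' @return a [parcellated_series()] of residuals.
#' @export
regress_motion <- function(series, trace) {
  if (nrow(series$data) != nrow(trace$params))
    stop_validation("series and motion trace differ in length")
  X <- cbind(1, as.matrix(trace$params))
  qr_x <- qr(X)
  resid <- qr.resid(qr_x, series$data)
  parcellated_series(resid, tr = series$tr, run_label = series$run_label,
                     region_ids = series$region_ids)
}

#' Motion quality-control summary
#'
#' Applies the conventional exclusion thresholds (3 mm translation, 3 deg
#' rotation) as a flag, not a hard failure.
#'
#' @param trace a [motion_trace()].
#' @param max_translation_mm,max_rotation_deg QC ceilings.
#' @return list with `delta`, `sigma`, `max_translation`, `max_rotation`,
#'   `pass`.
#' @export
motion_qc <- function(trace, max_translation_mm = 3, max_rotation_deg = 3) {
  p <- as.matrix(trace$params)
  max_tra <- max(abs(p[, 1:3]))
  max_rot <- max(abs(p[, 4:6]))
  list(delta = mean_displacement(trace),
       sigma = displacement_speed(trace),
       max_translation = max_tra,
       max_rotation = max_rot,
       pass = max_tra <= max_translation_mm && max_rot <= max_rotation_deg)
}
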