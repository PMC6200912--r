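## Regional metabolic-functional coupling.
##
## The most representative graph strength per region is the elementwise
## maximum over the neuronal networks' strength maps; both the max-GS map and
## the regional PET uptake are z-scored (sample sd) and correlated. The
## p-value transforms r into a t statistic with N - 2 degrees of freedom.

#' Elementwise maximum graph-strength map over neuronal networks
#'
#' @param strength_maps list of `graph_strength_map`s (or numeric vectors) of
#'   equal length, one per neuronal network.
#' @return numeric per-region vector.
#' @export
max_gs_map <- function(strength_maps) {
  if (length(strength_maps) == 0L)
    stop_validation("no neuronal networks: max-GS map undefined")
  vecs <- lapply(strength_maps, function(m)
    if (inherits(m, "graph_strength_map")) m$s else as.numeric(m))
  if (length(unique(lengths(vecs))) != 1L)
    stop_validation("strength maps differ in length")
  do.call(pmax, vecs)
}

#' Pearson correlation with a t-based p-value
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` against the t distribution with n - 2
#' degrees of freedom, two-sided. Sample skewness of both inputs is reported
#' alongside, characterizing the shape of the two regional distributions.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, non-constant.
#' @return object of class `coupling_result`: list with `r`, `p`, `n`,
#'   `gs_skewness` (of `x`), `pet_skewness` (of `y`).
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_validation("inputs differ in length")
  if (n < 3L) stop_validation("correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined for a constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n,
                 gs_skewness = sample_skewness(x),
                 pet_skewness = sample_skewness(y)),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("coupling_result: r = %.3f, p = %.3g, n = %d (skewness GS %.2f, PET %.2f)\n",
              x$r, x$p, x$n, x$gs_skewness, x$pet_skewness))
  invisible(x)
}

#' Graph-strength / PET coupling for one acquisition
#'
#' Builds the max-GS map from the neuronal networks' strength maps, z-scores
#' it and the PET map, and correlates.
#'
#' @param strength_maps list of `graph_strength_map`s for neuronal networks.
#' @param pet a `pet_roi_map` or numeric per-region uptake vector.
#' @return a `coupling_result`.
#' @export
gs_pet_coupling <- function(strength_maps, pet) {
  gs <- max_gs_map(strength_maps)
  petv <- if (inherits(pet, "pet_roi_map")) pet$values else as.numeric(pet)
  if (length(petv) != length(gs))
    stop_validation("PET map and strength maps differ in length")
  pearson_with_p(zscore(gs), zscore(petv))
}
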