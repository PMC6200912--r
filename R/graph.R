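## Edge-weight graphs and node strength.
##
## From a component's per-region z-map the edge weight between regions i and
## j is |z_i| + |z_j| - |z_i - z_j|, i.e. 2*min(|z_i|, |z_j|) when the two
## z-values share a sign and exactly 0 otherwise. Weights are normalized to
## [0, 1] by the matrix maximum (the 0-to-1 threshold grid is meaningless on
## raw z-derived weights), every threshold in {0, 0.01, ..., 1} is applied
## keeping entries >= threshold, and the mean over the 101 thresholded copies
## is the effective weight feeding node strength.

#' Edge-weight matrix from a component z-map
#'
#' @param zmap per-region z-values (length N >= 2).
#' @param normalize divide by the maximum entry so weights live in `[0, 1]`.
#' @return object of class `edge_weight_matrix`: list with `w` (N x N
#'   symmetric, zero diagonal) and `normalized` flag.
#' @export
edge_weights <- function(zmap, normalize = TRUE) {
  assert_finite(zmap, "zmap")
  n <- length(zmap)
  if (n < 2L) stop_validation("edge weights need N >= 2 regions")
  a <- abs(zmap)
  w <- outer(a, a, "+") - abs(outer(zmap, zmap, "-"))
  diag(w) <- 0
  mx <- max(w)
  if (all(zmap == 0))
    warning("all-zero z-map yields an all-zero edge-weight matrix")
  if (mx > 0 && isTRUE(normalize)) w <- w / mx
  structure(list(w = w, normalized = isTRUE(normalize) || mx == 0),
            class = "edge_weight_matrix")
}

#' Mean over the 0-to-1 threshold sweep, in closed form
#'
#' Each normalized weight is replaced by its mean over the 101 thresholded
#' copies (thresholds 0, 0.01, ..., 1; entries >= threshold survive, the rest
#' are zeroed): `w * (number of surviving thresholds) / 101`, where a weight
#' w survives the `floor(100 w) + 1` thresholds not exceeding it.
#'
#' @param w an [edge_weights()] result with entries in `[0, 1]`.
#' @return an `edge_weight_matrix` of effective weights.
#' @export
threshold_sweep <- function(w) {
  stopifnot(inherits(w, "edge_weight_matrix"))
  m <- w$w
  if (!w$normalized || any(m < 0) || any(m > 1))
    stop_validation("threshold sweep requires weights normalized to [0, 1]")
  k <- floor(100 * m)
  ## exact tie handling: count thresholds t = j/100 with t <= w, robust to
  ## floating-point representation of j/100
  bump <- (k + 1) / 100 <= m
  k <- k + bump
  structure(list(w = m * (k + 1) / 101, normalized = TRUE),
            class = "edge_weight_matrix")
}

#' Node graph strength
#'
#' Row sums of the effective edge-weight matrix (self-loops excluded because
#' the diagonal is zero by construction).
#'
#' @param w_eff an `edge_weight_matrix` (normally post-[threshold_sweep()]).
#' @param network network name for bookkeeping.
#' @param acquisition run label for bookkeeping.
#' @return object of class `graph_strength_map`: list with `s` (length N,
#'   nonnegative), `network`, `acquisition`.
#' @export
strength <- function(w_eff, network = NA_character_,
                     acquisition = NA_character_) {
  stopifnot(inherits(w_eff, "edge_weight_matrix"))
  m <- w_eff$w
  if (any(m < 0)) stop_validation("edge weights must be nonnegative")
  if (max(abs(m - t(m))) > 1e-12) stop_validation("edge weights must be symmetric")
  structure(list(s = rowSums(m), network = network, acquisition = acquisition),
            class = "graph_strength_map")
}

#' Full z-map to graph-strength pipeline for one component
#'
#' Convenience composition: standardize defensively, Eq.-style edge weights,
#' normalize, threshold sweep, strength.
#'
#' @inheritParams edge_weights
#' @inheritParams strength
#' @return a `graph_strength_map`.
#' @export
zmap_strength <- function(zmap, network = NA_character_,
                          acquisition = NA_character_) {
  strength(threshold_sweep(edge_weights(zmap, normalize = TRUE)),
           network = network, acquisition = acquisition)
}
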