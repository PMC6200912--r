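## Ratio-of-fit (ROF) variability statistics.
##
## For each network and acquisition, regions with graph strength strictly
## above half the network maximum are selected and compared to the binary
## network template (mask): ROF = (in-mask - out-of-mask) / mask size.
## The test-retest difference dROF = ROF_T1 - ROF_T2 (a missing, i.e.
## non-neuronal or undetected, acquisition contributes 0) and the mean of
## |dROF| over all nine networks summarize within-session variability; the
## acquisition with the higher ROF is the "best finding" carried forward.

#' Select supra-half-max graph-strength regions
#'
#' @param s a `graph_strength_map` (or bare numeric strength vector).
#' @param region_ids region ids labelling `s` (default `1:N`).
#' @return integer vector of selected region ids (strict `> max/2`).
#' @export
select_regions <- function(s, region_ids = NULL) {
  v <- if (inherits(s, "graph_strength_map")) s$s else as.numeric(s)
  if (is.null(region_ids)) region_ids <- seq_along(v)
  if (max(v) <= 0) {
    warning("all-zero strength map: no regions selected")
    return(integer(0))
  }
  region_ids[v > 0.5 * max(v)]
}

#' Ratio of fit of a selected region set against a network mask
#'
#' @param selected region ids selected by [select_regions()].
#' @param mask region ids of the network template (nonempty).
#' @param network,acquisition bookkeeping labels.
#' @param neuronal neuronal flag carried through to the record.
#' @return object of class `rof_record`: list with `network`, `acquisition`,
#'   `in_count`, `out_count`, `missing_count`, `mask_size`, `rof`,
#'   `neuronal`. ROF is kept at full precision; round only when reporting.
#' @export
rof <- function(selected, mask, network = NA_character_,
                acquisition = NA_character_, neuronal = NA) {
  if (length(mask) == 0L) stop_validation("empty mask")
  in_count <- length(intersect(selected, mask))
  out_count <- length(setdiff(selected, mask))
  mask_size <- length(unique(mask))
  structure(list(network = network, acquisition = acquisition,
                 in_count = in_count, out_count = out_count,
                 missing_count = mask_size - in_count, mask_size = mask_size,
                 rof = (in_count - out_count) / mask_size,
                 neuronal = neuronal),
            class = "rof_record")
}

#' @export
print.rof_record <- function(x, ...) {
  cat(sprintf("rof_record [%s/%s]: in %d, out %d, missing %d of %d, ROF %.2f\n",
              x$network, x$acquisition, x$in_count, x$out_count,
              x$missing_count, x$mask_size, x$rof))
  invisible(x)
}

#' Test-retest ROF difference
#'
#' `dROF = ROF_T1 - ROF_T2`; a missing acquisition (non-neuronal or
#' undetected network, passed as `NA`) contributes 0.
#'
#' @param rof_t1,rof_t2 scalar ROF values or `NA` for a missing acquisition.
#' @return scalar dROF.
#' @export
delta_rof <- function(rof_t1, rof_t2) {
  r1 <- ifelse(is.na(rof_t1), 0, rof_t1)
  r2 <- ifelse(is.na(rof_t2), 0, rof_t2)
  r1 - r2
}

#' Mean absolute dROF over the network set
#'
#' The denominator is the full network count (default 9) regardless of how
#' many networks were detected; networks missing in both acquisitions
#' contribute |0|.
#'
#' @param delta_rofs vector of dROF values (`NA` treated as 0).
#' @param n_networks denominator (defaults to `length(delta_rofs)`).
#' @return scalar mean |dROF|.
#' @export
mean_abs_delta_rof <- function(delta_rofs, n_networks = length(delta_rofs)) {
  d <- ifelse(is.na(delta_rofs), 0, delta_rofs)
  sum(abs(d)) / n_networks
}

#' Best acquisition for one network
#'
#' The neuronal acquisition with the higher ROF; if only one acquisition is
#' neuronal, that one; tie goes to T1; neither neuronal gives `NA`.
#'
#' @param rof_t1,rof_t2 scalar ROFs (`NA` when missing).
#' @param neuronal_t1,neuronal_t2 neuronal flags per acquisition.
#' @param labels run labels, default `c("T1", "T2")`.
#' @return run label or `NA_character_`.
#' @export
best_acquisition <- function(rof_t1, rof_t2, neuronal_t1 = TRUE,
                             neuronal_t2 = TRUE, labels = c("T1", "T2")) {
  ok1 <- isTRUE(neuronal_t1) && !is.na(rof_t1)
  ok2 <- isTRUE(neuronal_t2) && !is.na(rof_t2)
  if (!ok1 && !ok2) return(NA_character_)
  if (ok1 && !ok2) return(labels[1])
  if (!ok1 && ok2) return(labels[2])
  if (rof_t2 > rof_t1) labels[2] else labels[1]
}

#' Percentage of network instances classified neuronal
#'
#' Over the 2 runs x 9 networks = 18 instances of a session by default.
#'
#' @param neuronal logical vector of per-instance neuronal flags (`NA` =
#'   undetected = not neuronal).
#' @param n_total denominator (defaults to `length(neuronal)`).
#' @return integer percentage.
#' @export
percent_neuronal <- function(neuronal, n_total = length(neuronal)) {
  round(100 * sum(neuronal, na.rm = TRUE) / n_total)
}
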