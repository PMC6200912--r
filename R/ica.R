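## Spatial ICA, component fingerprints, neuronal classification and
## template-matching network assignment.
##
## The decomposition is spatial: the T x N series is modeled as
## X = A S with S a k x N matrix of spatially independent component maps and
## A the paired time courses. Sources are extracted with symmetric
## fixed-point FastICA (logcosh contrast) on PCA-whitened data; the
## orthonormal initial rotation is drawn from the supplied seed, so the
## decomposition is deterministic per seed. ICA's sign indeterminacy is fixed
## by flipping each component so its spatial skewness is nonnegative, and
## every component map is standardized to mean 0, sd 1 over regions before
## any graph computation.

FINGERPRINT_BANDS <- matrix(
  c(0, 0.008,  0.008, 0.02,  0.02, 0.05,  0.05, 0.1,  0.1, 0.25),
  ncol = 2, byrow = TRUE,
  dimnames = list(paste0("band_power_", 1:5), c("lo", "hi")))

#' Component set from a spatial ICA decomposition
#'
#' @param zmaps k x N matrix of standardized spatial z-maps.
#' @param timecourses k x T matrix of paired time courses.
#' @param tr repetition time, seconds.
#' @return object of class `component_set`.
#' @export
component_set <- function(zmaps, timecourses, tr) {
  stopifnot(nrow(zmaps) == nrow(timecourses))
  structure(list(zmaps = zmaps, timecourses = timecourses, tr = tr,
                 k = nrow(zmaps)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat("component_set:", x$k, "components,", ncol(x$zmaps), "regions,",
      ncol(x$timecourses), "time points\n")
  invisible(x)
}

## Symmetric FastICA with logcosh nonlinearity on pre-whitened k x n data.
## Returns the orthogonal unmixing rotation.
fastica_rotation <- function(Z, max_iter = 500L, tol = 1e-8) {
  k <- nrow(Z)
  n <- ncol(Z)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' Decompose a parcellated series into spatial independent components
#'
#' @param series a [parcellated_series()].
#' @param k number of components (default 30, the pipeline's standard order).
#' @param seed integer seed controlling the ICA initialization.
#' @return a [component_set()] with standardized, sign-aligned z-maps.
#' @export
decompose <- function(series, k = 30L, seed = 1L) {
  X <- series$data
  tpts <- nrow(X)
  n <- ncol(X)
  if (k >= tpts)
    stop_config("k = ", k, " components require more than k time points (T = ",
                tpts, ")")
  if (k > n)
    stop_config("k = ", k, " exceeds the number of regions (N = ", n, ")")
  assert_finite(X, "series")
  Xc <- X - rowMeans(X)                    # center each time point over regions
  sv <- svd(Xc, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  if (any(d < 1e-10 * d[1]))
    d <- pmax(d, 1e-10 * d[1])             # guard near-degenerate directions
  Z <- sqrt(n) * t(sv$v)                   # k x N whitened spatial data
  W <- with_seed(seed, fastica_rotation(Z))
  S <- W %*% Z                             # k x N spatial sources
  A <- sv$u %*% diag(d, k) %*% t(W) / sqrt(n)   # T x k time courses
  zmaps <- t(apply(S, 1L, zscore))
  flip <- ifelse(apply(zmaps, 1L, sample_skewness) < 0, -1, 1)
  zmaps <- zmaps * flip
  tcs <- t(A) * flip
  component_set(zmaps = zmaps, timecourses = tcs, tr = series$tr)
}

#' Compute the 11-dimensional fingerprint of one component
#'
#' Spatial features: degree of clustering (Gini concentration of `|z|`),
#' skewness, kurtosis and 32-bin entropy of the z-map. Temporal features:
#' one-lag autocorrelation, 32-bin entropy, and the periodogram power
#' fractions of five frequency bands (0-0.008, 0.008-0.02, 0.02-0.05,
#' 0.05-0.1, 0.1-0.25 Hz). A constant time course yields zero band powers and
#' autocorrelation with `degenerate = TRUE`.
#'
#' @param zmap per-region z-values of the component.
#' @param timecourse paired time course.
#' @param tr repetition time, seconds.
#' @return object of class `fingerprint` (named list of the 11 features plus
#'   a `degenerate` flag).
#' @export
compute_fingerprint <- function(zmap, timecourse, tr) {
  assert_finite(zmap, "zmap")
  assert_finite(timecourse, "timecourse")
  degenerate <- stats::sd(timecourse) == 0
  tc <- timecourse - mean(timecourse)
  if (degenerate) {
    ac <- 0
    bands <- stats::setNames(numeric(5L), rownames(FINGERPRINT_BANDS))
    tent <- 0
  } else {
    ac <- sum(tc[-length(tc)] * tc[-1]) / sum(tc^2)
    bands <- vapply(seq_len(5L), function(b)
      band_power_fraction(timecourse, tr,
                          FINGERPRINT_BANDS[b, "lo"],
                          FINGERPRINT_BANDS[b, "hi"]),
      numeric(1))
    names(bands) <- rownames(FINGERPRINT_BANDS)
    tent <- binned_entropy(timecourse)
  }
  fp <- c(list(clustering_degree = gini_concentration(zmap),
               spatial_skewness = sample_skewness(zmap),
               spatial_kurtosis = sample_kurtosis(zmap),
               spatial_entropy = binned_entropy(zmap),
               one_lag_autocorr = ac,
               temporal_entropy = tent),
          as.list(bands),
          list(degenerate = degenerate))
  structure(fp, class = "fingerprint")
}

#' Classify a component as neuronal or artifactual
#'
#' Default rule: neuronal iff the low-frequency power fraction
#' (0.008-0.05 Hz, the nearest fingerprint-band superset of the canonical
#' 0.01-0.05 Hz neuronal band) exceeds the high-frequency fraction
#' (0.1-0.25 Hz) and the spatial kurtosis stays below a ceiling. The score is
#' the low-band minus high-band fraction.
#'
#' @param fp a [compute_fingerprint()] result.
#' @param kurtosis_ceiling reject components whose spatial kurtosis meets or
#'   exceeds this ceiling (default 50, excluding single-spike maps only).
#' @return list with `neuronal` flag and `score`.
#' @export
classify_neuronal <- function(fp, kurtosis_ceiling = 50) {
  if (isTRUE(fp$degenerate)) {
    warning("degenerate fingerprint: classified non-neuronal")
    return(list(neuronal = FALSE, score = 0))
  }
  low <- fp$band_power_2 + fp$band_power_3
  high <- fp$band_power_5
  list(neuronal = low > high && fp$spatial_kurtosis < kurtosis_ceiling,
       score = low - high)
}

#' Goodness-of-fit of a component map against a binary network template
#'
#' Mean z inside the template minus mean z outside it.
#'
#' @param zmap per-region z-values.
#' @param template_ids region ids of the template mask.
#' @param region_ids region ids labelling `zmap` (default `1:N`).
#' @return scalar gof.
#' @export
goodness_of_fit <- function(zmap, template_ids, region_ids = seq_along(zmap)) {
  idx <- match(template_ids, region_ids)
  if (anyNA(idx))
    stop_validation("template references region ids absent from the map")
  if (length(idx) == 0L) stop_validation("empty template")
  if (length(idx) >= length(zmap))
    stop_validation("template covers every region; gof undefined")
  mean(zmap[idx]) - mean(zmap[-idx])
}

#' Assign the nine networks to components by greedy exclusive goodness-of-fit
#'
#' All (network, component) pairs compete simultaneously: the globally best
#' gof is assigned first, both parties are removed, and the process repeats.
#' A network whose winning component is classified non-neuronal stays in the
#' table flagged `neuronal = FALSE` (present but non-neuronal). Ties break
#' toward the lower component index, then the earlier template.
#'
#' @param components a [component_set()].
#' @param atlas a [roi_atlas()] supplying `rsn_templates`.
#' @param neuronal_flags optional logical vector per component (computed from
#'   fingerprints when omitted).
#' @return list with `assignments` (data.frame: network, component, gof,
#'   neuronal) and `unassigned` (character vector of leftover networks).
#' @export
assign_networks <- function(components, atlas, neuronal_flags = NULL) {
  nets <- names(atlas$rsn_templates)
  k <- components$k
  if (k < 1L) stop_validation("no components to assign")
  if (is.null(neuronal_flags)) {
    neuronal_flags <- vapply(seq_len(k), function(i)
      classify_neuronal(compute_fingerprint(components$zmaps[i, ],
                                            components$timecourses[i, ],
                                            components$tr))$neuronal,
      logical(1))
  }
  gof <- matrix(NA_real_, nrow = length(nets), ncol = k,
                dimnames = list(nets, NULL))
  for (nm in nets)
    for (i in seq_len(k))
      gof[nm, i] <- goodness_of_fit(components$zmaps[i, ],
                                    atlas$rsn_templates[[nm]],
                                    atlas$region_ids)
  open_nets <- nets
  open_comps <- seq_len(k)
  rows <- list()
  while (length(open_nets) > 0 && length(open_comps) > 0) {
    sub <- gof[open_nets, open_comps, drop = FALSE]
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    ## ties: lower component index first, then earlier network
    hits <- hits[order(open_comps[hits[, 2]], hits[, 1]), , drop = FALSE]
    nm <- open_nets[hits[1, 1]]
    ci <- open_comps[hits[1, 2]]
    rows[[nm]] <- data.frame(network = nm, component = ci, gof = gof[nm, ci],
                             neuronal = neuronal_flags[ci])
    open_nets <- setdiff(open_nets, nm)
    open_comps <- setdiff(open_comps, ci)
  }
  assignments <- do.call(rbind, rows[nets[nets %in% names(rows)]])
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = setdiff(nets, assignments$network))
}
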