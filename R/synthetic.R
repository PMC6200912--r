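## Synthetic parcellated BOLD generator.
##
## Emulates the statistical world the downstream analysis assumes: a brain
## parcellated into N regions, nine resting-state networks each occupying a
## disjoint region set, band-limited (0.01-0.05 Hz) neuronal sources mixed
## into member regions, high-frequency (>= 0.1 Hz) artifact sources spread
## over the whole parcellation, white measurement noise, rigid-body motion
## traces, and a PET uptake map linearly coupled to the ground-truth maximum
## graph-strength map.

RSN_NAMES <- c("auditory", "DMN", "ECNL", "ECNR", "salience",
               "sensorimotor", "VL", "VM", "VO")

NEURONAL_BAND <- c(0.01, 0.05)
ARTIFACT_BAND <- c(0.10, 0.25)

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' describe the test-scale world: 60 regions, nine networks of five regions
#' each, 480 time points at TR = 1 s (the acquisition length and repetition
#' time of the clinical protocol the pipeline targets), four high-frequency
#' artifact sources, source-to-noise amplitude ratio 4, no spatial leakage.
#'
#' @param n_regions number of atlas regions N (the full Lausanne-2008 scale is
#'   1015; 60 keeps tests fast).
#' @param n_networks number of embedded resting-state networks (<= 9 named
#'   canonically, more get generic names).
#' @param regions_per_network regions per network;
#'   `n_networks * regions_per_network` must not exceed `n_regions`.
#' @param run_length time points per acquisition (>= 64).
#' @param tr repetition time, seconds.
#' @param n_artifact_sources number of high-frequency artifact sources.
#' @param snr amplitude ratio of unit-sd sources to white noise; `Inf` gives a
#'   noiseless run.
#' @param leakage fraction of non-member regions onto which each network map
#'   leaks (default 0 = clean membership).
#' @param pet_coupling target Pearson correlation in `[0, 1]` between the
#'   simulated PET map and the ground-truth maximum graph-strength map.
#' @param drift_mm_per_tr linear drift added to the TraX motion parameter.
#' @param motion_jitter_sd white jitter sd on all six motion parameters.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 60L, n_networks = 9L,
                       regions_per_network = 5L, run_length = 480L, tr = 1,
                       n_artifact_sources = 4L, snr = 4, leakage = 0,
                       pet_coupling = 0.5, drift_mm_per_tr = 0,
                       motion_jitter_sd = 0, seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_networks = as.integer(n_networks),
              regions_per_network = as.integer(regions_per_network),
              run_length = as.integer(run_length), tr = tr,
              n_artifact_sources = as.integer(n_artifact_sources), snr = snr,
              leakage = leakage, pet_coupling = pet_coupling,
              drift_mm_per_tr = drift_mm_per_tr,
              motion_jitter_sd = motion_jitter_sd, seed = as.integer(seed))
  if (cfg$n_networks * cfg$regions_per_network > cfg$n_regions)
    stop_config("infeasible membership: ", cfg$n_networks, " networks x ",
                cfg$regions_per_network, " regions > ", cfg$n_regions,
                " regions")
  if (cfg$run_length < 64L) stop_config("run_length must be >= 64")
  if (cfg$tr <= 0) stop_config("tr must be positive")
  if (cfg$pet_coupling < 0 || cfg$pet_coupling > 1)
    stop_config("pet_coupling must lie in [0, 1]")
  if (cfg$leakage < 0 || cfg$leakage >= 1)
    stop_config("leakage must lie in [0, 1)")
  if (NEURONAL_BAND[2] > 1 / (2 * cfg$tr))
    stop_config("neuronal band exceeds Nyquist for tr = ", cfg$tr)
  structure(cfg, class = "sim_config")
}

#' Build a synthetic parcellation atlas with network templates
#'
#' Regions get consecutive integer labels starting at 1; the first
#' `n_networks * regions_per_network` regions are assigned to disjoint network
#' templates in blocks (deterministic, so membership doubles as ground truth).
#'
#' @param config a [sim_config()].
#' @return a [roi_atlas()] whose `rsn_templates` are the ground-truth masks.
#' @export
make_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  k <- config$n_networks
  rpn <- config$regions_per_network
  ids <- seq_len(n)
  nms <- if (k <= length(RSN_NAMES)) RSN_NAMES[seq_len(k)] else
    c(RSN_NAMES, paste0("net", seq(10L, k)))[seq_len(k)]
  templates <- lapply(seq_len(k), function(i) ids[((i - 1L) * rpn + 1L):(i * rpn)])
  names(templates) <- nms
  roi_atlas(region_ids = ids,
            region_names = data.frame(id = ids,
                                      name = sprintf("roi_%03d", ids)),
            rsn_templates = templates)
}

#' Materialize an atlas as a 3D label image
#'
#' Lays regions out as consecutive runs of `voxels_per_region` voxels on a
#' compact 3D grid (remaining voxels are 0 = background). Geometry carries no
#' meaning; it exists so the voxel-reduction route can be exercised.
#'
#' @param atlas a [roi_atlas()].
#' @param voxels_per_region voxels per region (default 1).
#' @return 3D integer array of region labels.
#' @export
atlas_label_image <- function(atlas, voxels_per_region = 1L) {
  n_vox <- length(atlas$region_ids) * voxels_per_region
  nx <- ceiling(n_vox^(1 / 3))
  ny <- ceiling(sqrt(n_vox / nx))
  nz <- ceiling(n_vox / (nx * ny))
  img <- integer(nx * ny * nz)
  img[seq_len(n_vox)] <- rep(atlas$region_ids, each = voxels_per_region)
  array(img, dim = c(nx, ny, nz))
}

## Ground-truth spatial maps: nonzero exactly on member regions (loadings
## 0.8-1.2) plus, when leakage > 0, a sampled fraction of non-members at
## reduced loading 0.2-0.5.
make_true_zmaps <- function(atlas, config) {
  n <- config$n_regions
  k <- config$n_networks
  z <- matrix(0, nrow = k, ncol = n,
              dimnames = list(names(atlas$rsn_templates), NULL))
  for (i in seq_len(k)) {
    members <- atlas$rsn_templates[[i]]
    z[i, members] <- stats::runif(length(members), 0.8, 1.2)
    if (config$leakage > 0) {
      out <- setdiff(atlas$region_ids, members)
      n_leak <- round(config$leakage * length(out))
      if (n_leak > 0) {
        leak <- sample(out, n_leak)
        z[i, leak] <- stats::runif(n_leak, 0.2, 0.5)
      }
    }
  }
  z
}

#' Simulate one resting-state acquisition on a parcellated atlas
#'
#' The region-by-time data are a linear mixture: each network contributes a
#' band-limited (0.01-0.05 Hz) unit-sd source time course weighted by its
#' ground-truth spatial map; artifact sources are band-limited to 0.1-0.25 Hz
#' and load diffusely on all regions; white noise has sd `1/snr`. Motion
#' traces are generated alongside and returned in the ground truth.
#'
#' @param atlas a [roi_atlas()] built by [make_atlas()].
#' @param config a [sim_config()].
#' @param seed integer seed for this run (defaults to `config$seed`).
#' @param run_label acquisition tag, e.g. `"T1"`.
#' @return list with `series` (a [parcellated_series()]) and `truth` (list:
#'   `network_membership`, `source_timecourses`, `source_type`, `true_zmaps`,
#'   `artifact_zmaps`, `pet_map`, `motion`).
#' @export
simulate_run <- function(atlas, config, seed = config$seed, run_label = "T1") {
  stopifnot(inherits(atlas, "roi_atlas"), inherits(config, "sim_config"))
  if (ARTIFACT_BAND[1] >= 1 / (2 * config$tr))
    stop_config("artifact band incompatible with tr = ", config$tr)
  tpts <- config$run_length
  n <- config$n_regions
  k <- config$n_networks
  with_seed(seed, {
    zmaps <- make_true_zmaps(atlas, config)
    neuronal_tc <- vapply(seq_len(k), function(i) {
      s <- fft_bandpass(stats::rnorm(tpts), config$tr,
                        NEURONAL_BAND[1], NEURONAL_BAND[2])
      s / stats::sd(s)
    }, numeric(tpts))                                  # T x k
    data <- neuronal_tc %*% zmaps

    n_art <- config$n_artifact_sources
    art_tc <- NULL
    art_maps <- NULL
    if (n_art > 0) {
      art_hi <- min(ARTIFACT_BAND[2], 0.9 / (2 * config$tr))
      art_tc <- vapply(seq_len(n_art), function(i) {
        s <- fft_bandpass(stats::rnorm(tpts), config$tr, ARTIFACT_BAND[1], art_hi)
        s / stats::sd(s)
      }, numeric(tpts))
      art_maps <- matrix(stats::rnorm(n_art * n, sd = 0.5), nrow = n_art)
      data <- data + art_tc %*% art_maps
    }
    if (is.finite(config$snr))
      data <- data + matrix(stats::rnorm(tpts * n, sd = 1 / config$snr),
                            nrow = tpts)

    motion <- simulate_motion(config,
                              drift_mm_per_tr = config$drift_mm_per_tr,
                              jitter_sd = config$motion_jitter_sd,
                              .inherit_rng = TRUE)
    max_gs <- truth_max_gs(zmaps)
    pet <- simulate_pet_from_zmaps(zmaps, config$pet_coupling, max_gs = max_gs)

    tc_all <- t(cbind(neuronal_tc, art_tc))            # sources x T
    truth <- list(
      network_membership = atlas$rsn_templates,
      source_timecourses = tc_all,
      source_type = c(rep("neuronal", k), rep("artifact", nrow(tc_all) - k)),
      true_zmaps = zmaps,
      max_gs = max_gs,
      artifact_zmaps = art_maps,
      pet_map = pet,
      motion = motion
    )
    list(series = parcellated_series(data, tr = config$tr,
                                     run_label = run_label,
                                     region_ids = atlas$region_ids),
         truth = truth)
  })
}

## Ground-truth maximum graph-strength map: run each true spatial map through
## the same Eq.-style graph stage the pipeline uses (standardize -> edge
## weights -> normalize -> threshold sweep -> strength) and take the
## elementwise maximum over networks.
truth_max_gs <- function(zmaps) {
  s <- vapply(seq_len(nrow(zmaps)), function(i) {
    w <- edge_weights(zscore(zmaps[i, ]), normalize = TRUE)
    strength(threshold_sweep(w))$s
  }, numeric(ncol(zmaps)))
  apply(s, 1L, max)
}

simulate_pet_from_zmaps <- function(zmaps, coupling, max_gs = NULL) {
  if (coupling < 0 || coupling > 1)
    stop_config("coupling must lie in [0, 1]")
  gs <- if (is.null(max_gs)) truth_max_gs(zmaps) else max_gs
  noise <- stats::rnorm(length(gs))
  coupling * zscore(gs) + sqrt(1 - coupling^2) * zscore(noise)
}

#' Simulate a regional PET uptake map coupled to ground-truth graph strength
#'
#' `pet = coupling * z(max-GS) + sqrt(1 - coupling^2) * z(noise)`, so the
#' expected Pearson correlation with the ground-truth maximum graph-strength
#' map equals `coupling` (exactly 1 when `coupling = 1`).
#'
#' @param truth ground truth from [simulate_run()] (or any list with a
#'   `true_zmaps` matrix; a cached `max_gs` map is reused when present).
#' @param coupling target correlation in `[0, 1]`.
#' @param seed integer seed.
#' @return numeric per-region uptake vector (z-scaled mixture).
#' @export
simulate_pet <- function(truth, coupling, seed = 1L) {
  with_seed(seed, simulate_pet_from_zmaps(truth$true_zmaps, coupling,
                                          max_gs = truth$max_gs))
}

#' Simulate a rigid-body motion parameter table
#'
#' @param config a [sim_config()] (supplies `run_length` and `tr`).
#' @param seed integer seed.
#' @param drift_mm_per_tr linear drift applied to TraX (mm per TR), starting
#'   at 0 for the first volume.
#' @param jitter_sd white jitter sd applied to all six parameters.
#' @param .inherit_rng internal: draw from the caller's RNG stream.
#' @return a [motion_trace()] with columns TraX, TraY, TraZ (mm) and RotX,
#'   RotY, RotZ (degrees).
#' @export
simulate_motion <- function(config, seed = 1L, drift_mm_per_tr = 0,
                            jitter_sd = 0, .inherit_rng = FALSE) {
  tpts <- config$run_length
  build <- function() {
    p <- matrix(0, nrow = tpts, ncol = 6,
                dimnames = list(NULL, c("TraX", "TraY", "TraZ",
                                        "RotX", "RotY", "RotZ")))
    p[, "TraX"] <- drift_mm_per_tr * (seq_len(tpts) - 1L)
    if (jitter_sd > 0)
      p <- p + matrix(stats::rnorm(tpts * 6, sd = jitter_sd), nrow = tpts)
    motion_trace(as.data.frame(p), tr = config$tr)
  }
  if (.inherit_rng) build() else with_seed(seed, build())
}
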