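test_that("decompose recovers planted sources up to permutation and sign", {
  cfg <- sim_config(n_regions = 60, n_networks = 3, regions_per_network = 5,
                    snr = Inf, n_artifact_sources = 0L, seed = 8L)
  r <- simulate_run(make_atlas(cfg), cfg)
  comps <- decompose(r$series, k = 3, seed = 1)
  best <- perm_match_cor(comps$zmaps, r$truth$true_zmaps)
  expect_true(all(best > 0.95))
  ## z-maps standardized, sign convention: skewness >= 0
  expect_true(all(abs(rowMeans(comps$zmaps)) < 1e-10))
  expect_true(all(abs(apply(comps$zmaps, 1, sd) - 1) < 1e-10))
  expect_true(all(apply(comps$zmaps, 1, sample_skewness) >= 0))
})

test_that("decompose is deterministic per seed and validates k", {
  cfg <- tiny_cfg()
  r <- simulate_run(make_atlas(cfg), cfg)
  a <- decompose(r$series, k = 12, seed = 4)
  b <- decompose(r$series, k = 12, seed = 4)
  expect_identical(a$zmaps, b$zmaps)
  expect_identical(a$timecourses, b$timecourses)
  expect_error(decompose(r$series, k = 481), class = "rsnvar_config_error")
  expect_error(decompose(r$series, k = 61), class = "rsnvar_config_error")
})

test_that("fingerprint features behave on constructed signals", {
  n_t <- 480L
  zmap <- zscore(rnorm(60))
  ## pure sinusoid on an exact DFT bin inside 0.02-0.05 Hz
  tc <- sin(2 * pi * (15 / 480) * seq_len(n_t))
  fp <- compute_fingerprint(zmap, tc, tr = 1)
  expect_gt(fp$band_power_3, 0.9)
  bands <- unlist(fp[paste0("band_power_", 1:5)])
  expect_true(all(bands >= 0) && sum(bands) <= 1 + 1e-12)
  ## scaling the time course leaves band fractions unchanged
  fp2 <- compute_fingerprint(zmap, 37.5 * tc, tr = 1)
  expect_equal(unlist(fp2[paste0("band_power_", 1:5)]), bands)
  ## white noise: negligible one-lag autocorrelation
  fpw <- withr::with_seed(11, compute_fingerprint(zmap, rnorm(1e4), tr = 1))
  expect_lt(abs(fpw$one_lag_autocorr), 0.05)
  ## symmetric map: near-zero spatial skewness
  sym <- c(-(1:30), 1:30) / 10
  fps <- compute_fingerprint(sym, tc, tr = 1)
  expect_equal(fps$spatial_skewness, 0)
  ## degenerate time course flagged, zero temporal features
  expect_warning(cl <- classify_neuronal(
    compute_fingerprint(zmap, rep(1, n_t), tr = 1)))
  expect_false(cl$neuronal)
})

test_that("classification agrees with generator labels", {
  cfg <- tiny_cfg()
  r <- simulate_run(make_atlas(cfg), cfg)
  z <- zscore(r$truth$true_zmaps[1, ])
  neuronal_tc <- r$truth$source_timecourses[1, ]
  art_idx <- which(r$truth$source_type == "artifact")[1]
  art_tc <- r$truth$source_timecourses[art_idx, ]
  expect_true(classify_neuronal(
    compute_fingerprint(z, neuronal_tc, cfg$tr))$neuronal)
  expect_false(classify_neuronal(
    compute_fingerprint(z, art_tc, cfg$tr))$neuronal)
  ## score is antisymmetric under swapping the two band fractions
  fp <- compute_fingerprint(z, neuronal_tc, cfg$tr)
  sc <- classify_neuronal(fp)$score
  swapped <- fp
  swapped$band_power_5 <- fp$band_power_2 + fp$band_power_3
  swapped$band_power_2 <- 0
  swapped$band_power_3 <- fp$band_power_5
  expect_equal(classify_neuronal(swapped)$score, -sc)
})

test_that("goodness_of_fit is the inside-minus-outside mean", {
  expect_equal(goodness_of_fit(c(2, 1, -1, -2), c(1, 2)), 3)
  ## self-match is maximal among equal-size templates
  z <- zscore(c(rep(3, 4), rep(0, 16)))
  self <- goodness_of_fit(z, 1:4)
  others <- sapply(1:4, function(s) goodness_of_fit(z, s + 1:4))
  expect_true(all(self > others))
  ## independent map: gof near 0
  set.seed(2)
  big <- rnorm(5000)
  expect_lt(abs(goodness_of_fit(big, 1:50)), 0.5)
  ## linear in z, invariant to additive shifts
  z4 <- c(0.3, -1, 2, 0.1)
  expect_equal(goodness_of_fit(3 * z4, c(1, 3)),
               3 * goodness_of_fit(z4, c(1, 3)))
  expect_equal(goodness_of_fit(z4 + 7, c(1, 3)), goodness_of_fit(z4, c(1, 3)))
  expect_error(goodness_of_fit(z4, integer(0)),
               class = "rsnvar_validation_error")
  expect_error(goodness_of_fit(z4, 1:4), class = "rsnvar_validation_error")
})

test_that("assign_networks is exclusive and recovers clean simulations", {
  cfg <- tiny_cfg()
  r <- simulate_run(make_atlas(cfg), cfg)
  comps <- decompose(r$series, k = 13, seed = 2)
  asn <- assign_networks(comps, make_atlas(cfg))
  expect_equal(anyDuplicated(asn$assignments$component), 0L)
  expect_setequal(asn$assignments$network, names(make_atlas(cfg)$rsn_templates))
  ## each assigned component matches its network's true map
  for (i in seq_len(nrow(asn$assignments))) {
    nm <- asn$assignments$network[i]
    ci <- asn$assignments$component[i]
    expect_gt(abs(cor(comps$zmaps[ci, ], r$truth$true_zmaps[nm, ])), 0.9)
  }
  ## 2 networks, 1 component: one assigned, one unassigned
  single <- component_set(comps$zmaps[1, , drop = FALSE],
                          comps$timecourses[1, , drop = FALSE], comps$tr)
  atlas2 <- make_atlas(sim_config(n_regions = 60, n_networks = 2,
                                  regions_per_network = 5))
  asn2 <- assign_networks(single, atlas2, neuronal_flags = TRUE)
  expect_equal(nrow(asn2$assignments), 1L)
  expect_length(asn2$unassigned, 1L)
})
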