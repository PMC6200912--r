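test_that("make_atlas partitions regions into disjoint templates", {
  atlas <- make_atlas(tiny_cfg())
  expect_length(atlas$region_ids, 60L)
  expect_length(atlas$rsn_templates, 9L)
  expect_true(all(lengths(atlas$rsn_templates) == 5L))
  all_members <- unlist(atlas$rsn_templates)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_length(setdiff(atlas$region_ids, all_members), 15L)

  ## exact partition case
  atlas2 <- make_atlas(sim_config(n_regions = 10, n_networks = 2,
                                  regions_per_network = 5))
  expect_setequal(unlist(atlas2$rsn_templates), atlas2$region_ids)

  expect_error(sim_config(n_regions = 4, n_networks = 9,
                          regions_per_network = 5),
               class = "rsnvar_config_error")
})

test_that("simulated sources are band-limited and mixing is faithful", {
  cfg <- sim_config(n_regions = 60L, n_networks = 1L,
                    regions_per_network = 5L, snr = Inf,
                    n_artifact_sources = 0L, seed = 42L)
  atlas <- make_atlas(cfg)
  r <- simulate_run(atlas, cfg)
  ## with no noise a member region's series is the source up to scale
  member <- atlas$rsn_templates[[1]][1]
  expect_gt(abs(cor(r$series$data[, member],
                    r$truth$source_timecourses[1, ])), 0.99)
  ## >= 90% of neuronal source power inside 0.01-0.05 Hz (brute-force
  ## periodogram integration; the generator filters in the DFT domain so the
  ## in-band fraction is essentially 1)
  frac <- rsnvar:::band_power_fraction(r$truth$source_timecourses[1, ],
                                       cfg$tr, 0.01, 0.05)
  expect_gt(frac, 0.9)
})

test_that("artifact sources fail the neuronal band test", {
  cfg <- tiny_cfg(n_artifact_sources = 3L)
  r <- simulate_run(make_atlas(cfg), cfg)
  art <- which(r$truth$source_type == "artifact")
  for (i in art) {
    tc <- r$truth$source_timecourses[i, ]
    expect_lt(rsnvar:::band_power_fraction(tc, cfg$tr, 0.01, 0.05), 0.1)
    expect_gt(rsnvar:::band_power_fraction(tc, cfg$tr, 0.1, 0.25), 0.9)
  }
})

test_that("generators are bit-identical for a fixed seed", {
  cfg <- tiny_cfg(motion_jitter_sd = 0.05)
  atlas <- make_atlas(cfg)
  a <- simulate_run(atlas, cfg, seed = 5L)
  b <- simulate_run(atlas, cfg, seed = 5L)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$motion$params, b$truth$motion$params)
  expect_identical(a$truth$pet_map, b$truth$pet_map)
  c <- simulate_run(atlas, cfg, seed = 6L)
  expect_false(identical(a$series$data, c$series$data))
})

test_that("simulate_pet hits its target coupling", {
  cfg <- tiny_cfg()
  truth <- simulate_run(make_atlas(cfg), cfg)$truth
  ## coupling 1: noise term vanishes exactly
  pet1 <- simulate_pet(truth, 1, seed = 1)
  gs <- max_gs_map(lapply(seq_len(nrow(truth$true_zmaps)), function(i)
    zmap_strength(zscore(truth$true_zmaps[i, ]))))
  expect_equal(cor(pet1, gs), 1, tolerance = 1e-12)
  ## coupling 0 at larger N: near-independence
  cfg2 <- sim_config(n_regions = 1000L, seed = 2L)
  truth2 <- simulate_run(make_atlas(cfg2), cfg2)$truth
  pet0 <- simulate_pet(truth2, 0, seed = 3)
  expect_lt(abs(cor(pet0, truth2$max_gs)), 0.1)
  expect_error(simulate_pet(truth, 1.5), class = "rsnvar_config_error")
})

test_that("simulate_motion builds drift and jitter as specified", {
  cfg <- tiny_cfg()
  zero <- simulate_motion(cfg, seed = 1)
  expect_true(all(as.matrix(zero$params) == 0))
  drift <- simulate_motion(cfg, seed = 1, drift_mm_per_tr = 0.1)
  expect_equal(drift$params$TraX, 0.1 * (0:(cfg$run_length - 1)))
  expect_true(all(drift$params$TraY == 0))
  j1 <- simulate_motion(cfg, seed = 9, jitter_sd = 0.05)
  j2 <- simulate_motion(cfg, seed = 9, jitter_sd = 0.05)
  expect_identical(j1$params, j2$params)
})

test_that("leakage knob widens the true maps", {
  cfg <- tiny_cfg(leakage = 0.2)
  r <- simulate_run(make_atlas(cfg), cfg)
  nz <- rowSums(r$truth$true_zmaps != 0)
  expect_true(all(nz > 5))   # members plus leaked regions
  clean <- simulate_run(make_atlas(tiny_cfg()), tiny_cfg())
  expect_true(all(rowSums(clean$truth$true_zmaps != 0) == 5))
})
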