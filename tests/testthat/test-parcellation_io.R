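test_that("nifti round-trips 3D and 4D arrays", {
  img <- array(as.integer(1:24), dim = c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".nii")
  nifti_write(img, path, datatype = "int32")
  back <- nifti_read(path)
  expect_identical(back$data, img)
  bold <- array(rnorm(2 * 3 * 4 * 5), dim = c(2, 3, 4, 5))
  path2 <- withr::local_tempfile(fileext = ".nii")
  nifti_write(bold, path2, pixdim = c(4, 4, 4, 2), datatype = "float64")
  back2 <- nifti_read(path2)
  expect_equal(back2$data, bold)
  expect_equal(back2$pixdim, c(4, 4, 4, 2))
})

test_that("atlas round-trips through NIfTI + TSV and validates ids", {
  atlas <- make_atlas(tiny_cfg())
  stem <- file.path(withr::local_tempdir(), "atlas")
  files <- write_atlas(atlas, stem)
  back <- read_atlas(files[["image"]], files[["labels"]], files[["templates"]])
  expect_identical(back$region_ids, atlas$region_ids)
  expect_identical(back$rsn_templates, atlas$rsn_templates)

  ## duplicate id in the label table
  labs <- read.delim(files[["labels"]])
  labs$id[2] <- labs$id[1]
  dup <- file.path(withr::local_tempdir(), "dup.tsv")
  write.table(labs, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(NULL, dup, files[["templates"]]),
               class = "rsnvar_validation_error")

  ## template referencing an unknown id, named in the message
  tmpl <- read.delim(files[["templates"]])
  tmpl$region_id[1] <- 9999L
  badt <- file.path(withr::local_tempdir(), "tmpl.tsv")
  write.table(tmpl, badt, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(NULL, files[["labels"]], badt), "9999")
})

test_that("extract_series reduces voxels by the unweighted mean", {
  atlas <- make_atlas(sim_config(n_regions = 10, n_networks = 2,
                                 regions_per_network = 5))
  atlas$label_image <- atlas_label_image(atlas, voxels_per_region = 2L)
  dims <- dim(atlas$label_image)
  ## constant image -> constant series
  bold <- array(5, dim = c(dims, 3L))
  s <- extract_series(bold, atlas)
  expect_true(all(s$data == 5))
  ## two-voxel region with values 1 and 3 -> 2
  bold[, , , 1][atlas$label_image == 1] <- c(1, 3)
  expect_equal(unname(extract_series(bold, atlas)$data[1, "1"]), 2)
  ## one-voxel regions reproduce the voxel series exactly
  atlas1 <- atlas
  atlas1$label_image <- atlas_label_image(atlas1, voxels_per_region = 1L)
  b1 <- array(rnorm(prod(dim(atlas1$label_image)) * 4),
              dim = c(dim(atlas1$label_image), 4L))
  s1 <- extract_series(b1, atlas1)
  vox <- which(atlas1$label_image == 7)
  flat <- matrix(b1, ncol = 4)
  expect_equal(unname(s1$data[, "7"]), flat[vox, ])
  ## grid mismatch
  expect_error(extract_series(array(0, dim = c(2, 2, 2, 3)), atlas),
               class = "rsnvar_validation_error")
})

test_that("extract_series commutes with region relabeling", {
  cfg <- sim_config(n_regions = 10, n_networks = 2, regions_per_network = 5)
  atlas <- make_atlas(cfg)
  atlas$label_image <- atlas_label_image(atlas)
  bold <- array(rnorm(prod(dim(atlas$label_image)) * 3),
                dim = c(dim(atlas$label_image), 3L))
  s <- extract_series(bold, atlas)
  ## relabel region r -> 11 - r
  perm <- atlas
  perm$region_ids <- as.integer(11L - atlas$region_ids)
  perm$region_names <- data.frame(id = perm$region_ids,
                                  name = atlas$region_names$name)
  perm$rsn_templates <- lapply(atlas$rsn_templates, function(v) 11L - v)
  perm$label_image <- array(ifelse(atlas$label_image > 0,
                                   11L - atlas$label_image, 0L),
                            dim = dim(atlas$label_image))
  class(perm) <- "roi_atlas"
  perm <- roi_atlas(sort(perm$region_ids), rsn_templates = perm$rsn_templates,
                    label_image = perm$label_image)
  sp <- extract_series(bold, perm)
  for (r in atlas$region_ids)
    expect_equal(unname(s$data[, as.character(r)]),
                 unname(sp$data[, as.character(11L - r)]))
})

test_that("pet_roi_means mirrors extract_series on one volume", {
  atlas <- make_atlas(sim_config(n_regions = 10, n_networks = 2,
                                 regions_per_network = 5))
  atlas$label_image <- atlas_label_image(atlas, voxels_per_region = 2L)
  img <- array(3.5, dim = dim(atlas$label_image))
  expect_true(all(pet_roi_means(img, atlas)$values == 3.5))
  img[atlas$label_image == 4] <- c(2, 4)
  expect_equal(pet_roi_means(img, atlas)$values[4], 3)
  expect_error(pet_roi_means(array(0, dim = c(1, 1, 1)), atlas),
               class = "rsnvar_validation_error")
})

test_that("series TSV round-trip is lossless and concatenation behaves", {
  cfg <- tiny_cfg()
  r <- simulate_run(make_atlas(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series(r$series, path)
  back <- read_series(path, tr = cfg$tr, run_label = "T1")
  expect_equal(back$data, r$series$data, tolerance = 1e-12)
  expect_identical(back$region_ids, r$series$region_ids)

  r2 <- simulate_run(make_atlas(cfg), cfg, seed = 43L, run_label = "T2")
  cc <- concatenate_runs(r$series, r2$series)
  expect_equal(nrow(cc$data), 960L)
  expect_identical(cc$run_label, "concat")
  ## standardized join: each region of a duplicated run has mean 0
  dup <- concatenate_runs(r$series, r$series, standardize = TRUE)
  expect_true(all(abs(colMeans(dup$data)) < 1e-12))
  ## no standardization preserves raw values
  raw <- concatenate_runs(r$series, r2$series, standardize = FALSE)
  expect_equal(raw$data[1:480, ], r$series$data)

  bad <- r2$series; bad$tr <- 2
  expect_error(concatenate_runs(r$series, bad),
               class = "rsnvar_validation_error")
})
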