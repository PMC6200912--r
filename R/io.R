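## Region-level containers and standard-format I/O.
##
## Everything downstream of the voxel images is region-level: an atlas of N
## labeled regions carrying the nine network templates, and T x N time-series
## matrices. TSV is the primary interchange format; NIfTI only appears where
## voxel images enter (label image, 4D BOLD, PET volume).

#' Parcellation atlas
#'
#' @param region_ids ordered vector of unique positive integer labels.
#' @param region_names data.frame with columns `id`, `name`.
#' @param rsn_templates named list mapping network names to region-id vectors
#'   (the binary network template masks).
#' @param label_image optional 3D integer array of region labels.
#' @return object of class `roi_atlas`.
#' @export
roi_atlas <- function(region_ids, region_names = NULL, rsn_templates = list(),
                      label_image = NULL) {
  region_ids <- as.integer(region_ids)
  if (length(region_ids) < 2L) stop_validation("an atlas needs N >= 2 regions")
  if (anyDuplicated(region_ids)) stop_validation("duplicate region ids")
  if (any(region_ids < 1L)) stop_validation("region ids must be positive")
  if (is.null(region_names))
    region_names <- data.frame(id = region_ids,
                               name = sprintf("roi_%03d", region_ids))
  for (nm in names(rsn_templates)) {
    bad <- setdiff(rsn_templates[[nm]], region_ids)
    if (length(bad) > 0)
      stop_validation("template '", nm, "' references unknown region id(s): ",
                      paste(bad, collapse = ", "))
    rsn_templates[[nm]] <- as.integer(rsn_templates[[nm]])
  }
  structure(list(region_ids = region_ids, region_names = region_names,
                 rsn_templates = rsn_templates, label_image = label_image),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("roi_atlas:", length(x$region_ids), "regions,",
      length(x$rsn_templates), "network templates\n")
  invisible(x)
}

#' Parcellated BOLD time series
#'
#' @param data T x N numeric matrix (time points by regions).
#' @param tr repetition time, seconds.
#' @param run_label acquisition tag, e.g. `"T1"`, `"T2"`, `"concat"`.
#' @param region_ids column labels; defaults to `1:N`.
#' @return object of class `parcellated_series`.
#' @export
parcellated_series <- function(data, tr, run_label = "run",
                               region_ids = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop_validation("a series needs T >= 2 time points")
  if (anyNA(data) || !all(is.finite(data)))
    stop_validation("series contains missing or non-finite values")
  if (tr <= 0) stop_validation("tr must be positive")
  if (is.null(region_ids)) region_ids <- seq_len(ncol(data))
  colnames(data) <- as.character(region_ids)
  structure(list(data = data, tr = tr, run_label = run_label,
                 region_ids = as.integer(region_ids)),
            class = "parcellated_series")
}

#' @export
print.parcellated_series <- function(x, ...) {
  cat("parcellated_series [", x$run_label, "]: ", nrow(x$data),
      " time points x ", ncol(x$data), " regions, TR = ", x$tr, " s\n",
      sep = "")
  invisible(x)
}

#' Write / read an atlas as NIfTI label image + TSV tables
#'
#' `write_atlas()` emits `<stem>.nii` (only when the atlas carries or is asked
#' to materialize a label image), `<stem>_labels.tsv` (columns id, name) and
#' `<stem>_templates.tsv` (columns network, region_id, one row per member).
#'
#' @param atlas a [roi_atlas()].
#' @param stem path stem for the output files.
#' @param label_image write a label image (materialized via
#'   [atlas_label_image()] when the atlas has none).
#' @return named character vector of the files written, invisibly.
#' @export
write_atlas <- function(atlas, stem, label_image = TRUE) {
  files <- c(labels = paste0(stem, "_labels.tsv"),
             templates = paste0(stem, "_templates.tsv"))
  write_tsv(atlas$region_names, files[["labels"]])
  tmpl <- do.call(rbind, lapply(names(atlas$rsn_templates), function(nm)
    data.frame(network = nm, region_id = atlas$rsn_templates[[nm]])))
  write_tsv(tmpl, files[["templates"]])
  if (isTRUE(label_image)) {
    img <- atlas$label_image
    if (is.null(img)) img <- atlas_label_image(atlas)
    files <- c(files, image = paste0(stem, ".nii"))
    nifti_write(img, files[["image"]], datatype = "int32")
  }
  invisible(files)
}

#' @rdname write_atlas
#' @param label_image_path NIfTI label image path, or `NULL` for a
#'   table-only atlas.
#' @param label_table_path TSV with columns `id`, `name`.
#' @param template_table_path TSV with columns `network`, `region_id`.
#' @export
read_atlas <- function(label_image_path, label_table_path,
                       template_table_path) {
  labels <- read_tsv(label_table_path)
  if (!all(c("id", "name") %in% names(labels)))
    stop_validation("label table needs columns id, name")
  if (anyDuplicated(labels$id))
    stop_validation("label table has duplicate id(s): ",
                    paste(unique(labels$id[duplicated(labels$id)]),
                          collapse = ", "))
  ord <- order(labels$id)
  labels <- labels[ord, , drop = FALSE]
  tmpl_tab <- read_tsv(template_table_path)
  if (!all(c("network", "region_id") %in% names(tmpl_tab)))
    stop_validation("template table needs columns network, region_id")
  bad <- setdiff(tmpl_tab$region_id, labels$id)
  if (length(bad) > 0)
    stop_validation("template references unknown region id(s): ",
                    paste(bad, collapse = ", "))
  templates <- split(as.integer(tmpl_tab$region_id), tmpl_tab$network)
  templates <- templates[unique(tmpl_tab$network)]   # preserve file order
  img <- NULL
  if (!is.null(label_image_path)) img <- nifti_read(label_image_path)$data
  roi_atlas(region_ids = labels$id, region_names = labels,
            rsn_templates = templates, label_image = img)
}

#' Reduce a 4D BOLD image to a parcellated series
#'
#' Each region's value at each time point is the unweighted mean over that
#' region's voxels in the atlas label image; columns follow `region_ids`.
#'
#' @param bold 4D array or the list returned by [nifti_read()].
#' @param atlas a [roi_atlas()] carrying a `label_image` on the same grid.
#' @param tr repetition time, seconds.
#' @param run_label acquisition tag.
#' @return a [parcellated_series()].
#' @export
extract_series <- function(bold, atlas, tr = 1, run_label = "run") {
  if (is.list(bold) && !is.null(bold$data)) {
    if (length(bold$pixdim) >= 4L) tr <- bold$pixdim[4L]
    bold <- bold$data
  }
  lab <- atlas$label_image
  if (is.null(lab)) stop_validation("atlas carries no label image")
  if (!identical(dim(bold)[1:3], dim(lab)))
    stop_validation("BOLD grid ", paste(dim(bold)[1:3], collapse = "x"),
                    " does not match label image ",
                    paste(dim(lab), collapse = "x"))
  tpts <- dim(bold)[4L]
  flat <- matrix(bold, ncol = tpts)                  # voxels x T
  lab_v <- as.integer(lab)
  keep <- lab_v %in% atlas$region_ids
  sums <- rowsum(flat[keep, , drop = FALSE], group = lab_v[keep])
  counts <- tabulate(lab_v[keep])[as.integer(rownames(sums))]
  means <- sums / counts                             # regions x T, id-sorted
  found <- as.integer(rownames(sums))
  missing <- setdiff(atlas$region_ids, found)
  if (length(missing) > 0)
    stop_validation("region id(s) absent from label image: ",
                    paste(missing, collapse = ", "))
  ord <- match(atlas$region_ids, found)
  parcellated_series(t(means[ord, , drop = FALSE]), tr = tr,
                     run_label = run_label, region_ids = atlas$region_ids)
}

#' Reduce a 3D PET volume to regional means
#'
#' @param pet 3D array or [nifti_read()] result.
#' @param atlas a [roi_atlas()] with a label image on the same grid.
#' @param global_scale divide by the mean over all regions before returning
#'   (global-signal normalization; off by default).
#' @return a `pet_roi_map`: list with `values` (length N, atlas order) and
#'   `zscored` flag.
#' @export
pet_roi_means <- function(pet, atlas, global_scale = FALSE) {
  if (is.list(pet) && !is.null(pet$data)) pet <- pet$data
  if (length(dim(pet)) != 3L) stop_validation("PET image must be 3D")
  ## reuse the 4D reduction on a duplicated volume (series need T >= 2)
  series <- extract_series(array(c(pet, pet), dim = c(dim(pet), 2L)), atlas)
  values <- as.numeric(series$data[1L, ])
  if (isTRUE(global_scale)) values <- values / mean(values)
  pet_roi_map(values)
}

#' @rdname pet_roi_means
#' @param values length-N vector of regional uptake values.
#' @param zscored whether `values` are already z-scores over regions.
#' @export
pet_roi_map <- function(values, zscored = FALSE) {
  assert_finite(values, "PET values")
  structure(list(values = as.numeric(values), zscored = isTRUE(zscored)),
            class = "pet_roi_map")
}

#' Concatenate two acquisitions along time
#'
#' By default each run is per-region demeaned and variance-normalized before
#' joining, removing inter-run scale/offset differences.
#'
#' @param run1,run2 [parcellated_series()] on the same atlas with equal TR.
#' @param standardize standardize each run per region before joining.
#' @return a [parcellated_series()] with `run_label = "concat"`.
#' @export
concatenate_runs <- function(run1, run2, standardize = TRUE) {
  if (!identical(run1$region_ids, run2$region_ids))
    stop_validation("runs are on different region sets")
  if (!isTRUE(all.equal(run1$tr, run2$tr)))
    stop_validation("runs have different TR (", run1$tr, " vs ", run2$tr, ")")
  std <- function(m) {
    if (!standardize) return(m)
    sds <- apply(m, 2L, stats::sd)
    sds[sds == 0] <- 1
    sweep(sweep(m, 2L, colMeans(m)), 2L, sds, "/")
  }
  parcellated_series(rbind(std(run1$data), std(run2$data)), tr = run1$tr,
                     run_label = "concat", region_ids = run1$region_ids)
}

#' Write / read a parcellated series as TSV
#'
#' Rows are time points; columns are region ids (header row).
#'
#' @param series a [parcellated_series()].
#' @param path TSV path.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series$data, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_series
#' @param tr,run_label metadata to attach on read.
#' @export
read_series <- function(path, tr = 1, run_label = "run") {
  df <- read_tsv(path)
  parcellated_series(as.matrix(df), tr = tr, run_label = run_label,
                     region_ids = as.integer(names(df)))
}
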