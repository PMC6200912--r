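## End-to-end orchestration: synthetic "patient" fixtures, full analysis of a
## two-acquisition session, and the published-table arithmetic check.

ANALYSIS_ACQS <- c("T1", "T2", "concat")

#' Write a complete synthetic patient fixture
#'
#' Generates two acquisitions plus atlas, PET map, motion traces and a
#' ground-truth sidecar, and writes them as plain-text files (series TSVs,
#' atlas NIfTI + TSVs, PET TSV, motion TSVs, truth JSON). Byte-identical for
#' a fixed config.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of files written, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  atlas <- make_atlas(config)
  t1 <- simulate_run(atlas, config, seed = config$seed, run_label = "T1")
  t2 <- simulate_run(atlas, config, seed = config$seed + 1L, run_label = "T2")

  p <- function(f) file.path(out_dir, f)
  files <- c(run1 = p("run_T1.tsv"), run2 = p("run_T2.tsv"),
             pet = p("pet.tsv"), motion1 = p("motion_T1.tsv"),
             motion2 = p("motion_T2.tsv"), truth = p("truth.json"))
  write_series(t1$series, files[["run1"]])
  write_series(t2$series, files[["run2"]])
  write_tsv(data.frame(region_id = atlas$region_ids,
                       uptake = round(t1$truth$pet_map, 10)),
            files[["pet"]])
  write_motion(t1$truth$motion, files[["motion1"]])
  write_motion(t2$truth$motion, files[["motion2"]])
  files <- c(files, write_atlas(atlas, file.path(out_dir, "atlas")))
  truth_json <- list(
    config = unclass(config),
    config_checksum = config_checksum(unclass(config)),
    network_membership = atlas$rsn_templates,
    source_type = t1$truth$source_type,
    true_zmaps_T1 = round(t1$truth$true_zmaps, 10),
    true_zmaps_T2 = round(t2$truth$true_zmaps, 10)
  )
  jsonlite::write_json(truth_json, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}

#' Load a synthetic patient fixture written by [run_simulate()]
#'
#' @param dir fixture directory.
#' @param tr repetition time of the stored series (read from the truth
#'   sidecar when present).
#' @return list with `atlas`, `runs` (list of two [parcellated_series()]),
#'   `motion` (list of two [motion_trace()]), `pet` (`pet_roi_map`), `truth`.
#' @export
read_patient <- function(dir, tr = NULL) {
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  if (is.null(tr)) tr <- if (!is.null(truth)) truth$config$tr else 1
  atlas <- read_atlas(file.path(dir, "atlas.nii"),
                      file.path(dir, "atlas_labels.tsv"),
                      file.path(dir, "atlas_templates.tsv"))
  runs <- list(
    T1 = read_series(file.path(dir, "run_T1.tsv"), tr = tr, run_label = "T1"),
    T2 = read_series(file.path(dir, "run_T2.tsv"), tr = tr, run_label = "T2"))
  motion <- list(T1 = read_motion(file.path(dir, "motion_T1.tsv"), tr = tr),
                 T2 = read_motion(file.path(dir, "motion_T2.tsv"), tr = tr))
  pet <- pet_roi_map(read_tsv(file.path(dir, "pet.tsv"))$uptake)
  list(atlas = atlas, runs = runs, motion = motion, pet = pet, truth = truth)
}

analyze_acquisition <- function(series, atlas, k, seed) {
  comps <- decompose(series, k = k, seed = seed)
  flags <- vapply(seq_len(comps$k), function(i)
    classify_neuronal(compute_fingerprint(comps$zmaps[i, ],
                                          comps$timecourses[i, ],
                                          comps$tr))$neuronal, logical(1))
  asn <- assign_networks(comps, atlas, neuronal_flags = flags)
  records <- list()
  strengths <- list()
  for (nm in names(atlas$rsn_templates)) {
    row <- asn$assignments[asn$assignments$network == nm, ]
    if (nrow(row) == 0L) {
      records[[nm]] <- rof(integer(0), atlas$rsn_templates[[nm]],
                           network = nm, acquisition = series$run_label,
                           neuronal = FALSE)
      records[[nm]]$rof <- NA_real_        # undetected: no ROF
      next
    }
    zmap <- comps$zmaps[row$component, ]
    gsm <- zmap_strength(zmap, network = nm, acquisition = series$run_label)
    strengths[[nm]] <- gsm
    sel <- select_regions(gsm, atlas$region_ids)
    records[[nm]] <- rof(sel, atlas$rsn_templates[[nm]], network = nm,
                         acquisition = series$run_label,
                         neuronal = row$neuronal)
  }
  list(components = comps, assignment = asn, records = records,
       strengths = strengths, neuronal_flags = flags)
}

#' Analyze a two-acquisition session end to end
#'
#' Pipeline order: motion regression, spatial ICA per acquisition (T1, T2 and
#' their standardized concatenation), fingerprint classification, greedy
#' template assignment, per-network graph strength, half-max region
#' selection, ROF / dROF / mean |dROF|, best-acquisition selection, and
#' PET-coupling for the best and concatenated data.
#'
#' @param patient list as returned by [read_patient()] (or an equivalent
#'   in-memory assembly with `atlas`, `runs`, `motion`, `pet`).
#' @param k ICA component count (default 30).
#' @param seed integer seed for the decompositions.
#' @param out_dir optional directory for the report bundle (Table-1-style
#'   TSV, variability JSON, coupling JSONs, QC JSON, run log).
#' @return list of class `rsn_report` with elements `rof_table`,
#'   `variability`, `best`, `coupling`, `qc`, `acquisitions`.
#' @export
run_analyze <- function(patient, k = 30L, seed = 1L, out_dir = NULL) {
  atlas <- patient$atlas
  nets <- names(atlas$rsn_templates)
  cleaned <- list(
    T1 = regress_motion(patient$runs$T1, patient$motion$T1),
    T2 = regress_motion(patient$runs$T2, patient$motion$T2))
  cleaned$concat <- concatenate_runs(cleaned$T1, cleaned$T2,
                                     standardize = TRUE)
  res <- lapply(cleaned, analyze_acquisition, atlas = atlas, k = k,
                seed = seed)

  ## Table-1-style per-network summary; ROF reported only for neuronal
  ## detections, mirroring the published layout.
  reported_rof <- function(rec) if (isTRUE(rec$neuronal)) rec$rof else NA_real_
  rof_table <- do.call(rbind, lapply(nets, function(nm) {
    r1 <- res$T1$records[[nm]]; r2 <- res$T2$records[[nm]]
    rc <- res$concat$records[[nm]]
    data.frame(network = nm,
               in_t1 = r1$in_count, out_t1 = r1$out_count,
               rof_t1 = reported_rof(r1), neuronal_t1 = isTRUE(r1$neuronal),
               in_t2 = r2$in_count, out_t2 = r2$out_count,
               rof_t2 = reported_rof(r2), neuronal_t2 = isTRUE(r2$neuronal),
               delta_rof = delta_rof(reported_rof(r1), reported_rof(r2)),
               rof_concat = reported_rof(rc),
               neuronal_concat = isTRUE(rc$neuronal))
  }))

  best <- vapply(nets, function(nm)
    best_acquisition(rof_table$rof_t1[rof_table$network == nm],
                     rof_table$rof_t2[rof_table$network == nm],
                     rof_table$neuronal_t1[rof_table$network == nm],
                     rof_table$neuronal_t2[rof_table$network == nm]),
    character(1))

  variability <- list(
    delta_rof = stats::setNames(rof_table$delta_rof, nets),
    mean_abs_delta_rof = mean_abs_delta_rof(rof_table$delta_rof,
                                            n_networks = length(nets)),
    percent_neuronal = percent_neuronal(
      c(rof_table$neuronal_t1, rof_table$neuronal_t2)),
    best_acquisition = best)

  ## PET coupling: best = each network's best-acquisition strength map,
  ## neuronal networks only; concat = neuronal networks of the concatenated
  ## decomposition.
  best_maps <- list()
  for (nm in nets) {
    b <- best[[nm]]
    if (!is.na(b) && !is.null(res[[b]]$strengths[[nm]]))
      best_maps[[nm]] <- res[[b]]$strengths[[nm]]
  }
  concat_maps <- res$concat$strengths[
    vapply(nets, function(nm) isTRUE(res$concat$records[[nm]]$neuronal),
           logical(1))]
  coupling <- list(
    best = if (length(best_maps) > 0)
      gs_pet_coupling(best_maps, patient$pet) else NULL,
    concat = if (length(concat_maps) > 0)
      gs_pet_coupling(concat_maps, patient$pet) else NULL)

  qc <- list(T1 = motion_qc(patient$motion$T1),
             T2 = motion_qc(patient$motion$T2))

  report <- structure(list(rof_table = rof_table, variability = variability,
                           best = best, coupling = coupling, qc = qc,
                           acquisitions = res, seed = seed, k = k),
                      class = "rsn_report")
  if (!is.null(out_dir)) write_report(report, out_dir, patient = patient)
  report
}

#' @export
print.rsn_report <- function(x, ...) {
  cat("rsn_report: mean |dROF| =",
      sprintf("%.2f", x$variability$mean_abs_delta_rof),
      "| neuronal", x$variability$percent_neuronal, "% of",
      2 * nrow(x$rof_table), "network instances\n")
  tab <- x$rof_table[, c("network", "rof_t1", "rof_t2", "delta_rof",
                         "rof_concat")]
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

write_report <- function(report, out_dir, patient = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = report$seed, k = report$k,
               config_checksum = config_checksum(
                 list(seed = report$seed, k = report$k)))
  tab <- report$rof_table
  tab[, c("rof_t1", "rof_t2", "delta_rof", "rof_concat")] <-
    round(tab[, c("rof_t1", "rof_t2", "delta_rof", "rof_concat")], 2)
  write_tsv(tab, file.path(out_dir, "rof_table.tsv"))
  jsonlite::write_json(c(meta, report$variability),
                       file.path(out_dir, "variability.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(meta, lapply(report$coupling, unclass)),
                       file.path(out_dir, "coupling.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(meta, report$qc), file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ## figure-style region classification per network and acquisition
  cls <- list()
  for (acq in names(report$acquisitions)) {
    recs <- report$acquisitions[[acq]]$records
    strengths <- report$acquisitions[[acq]]$strengths
    atlas_ids <- if (!is.null(patient)) patient$atlas$region_ids else NULL
    for (nm in names(recs)) {
      gsm <- strengths[[nm]]
      if (is.null(gsm) || is.null(atlas_ids)) next
      sel <- select_regions(gsm, atlas_ids)
      mask <- patient$atlas$rsn_templates[[nm]]
      cls[[length(cls) + 1L]] <- data.frame(
        acquisition = acq, network = nm,
        region_id = c(intersect(sel, mask), setdiff(mask, sel),
                      setdiff(sel, mask)),
        category = rep(c("in_selected", "missed", "outside_selected"),
                       c(length(intersect(sel, mask)),
                         length(setdiff(mask, sel)),
                         length(setdiff(sel, mask)))))
    }
  }
  if (length(cls) > 0)
    write_tsv(do.call(rbind, cls), file.path(out_dir, "region_classes.tsv"))
  log_lines <- c(
    paste0("seed=", report$seed, " k=", report$k,
           " checksum=", meta$config_checksum),
    paste0("mean_abs_delta_rof=",
           sprintf("%.4f", report$variability$mean_abs_delta_rof)),
    paste0("percent_neuronal=", report$variability$percent_neuronal),
    "conventions: missing acquisition dROF treated as 0; ROF reported for neuronal detections only; weights normalized per component")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Recompute the published variability arithmetic from a ROF table
#'
#' Reads a Table-1-layout TSV (columns `patient`, `network`, `rof_t1`,
#' `rof_t2`, `delta_rof`; `NA` marks a missing acquisition), recomputes every
#' dROF as `ROF_T1 - ROF_T2` with missing values contributing 0, compares to
#' the stored dROF column at 2 decimals, and recomputes each patient's mean
#' |dROF| over its nine networks.
#'
#' @param path TSV path; defaults to the packaged transcription of the
#'   published table.
#' @return list with `n_cells`, `n_match`, `mismatches` (data.frame),
#'   `mean_abs_delta_rof` (named per patient), `recomputed` (full table).
#' @export
run_table1_check <- function(path = system.file("extdata", "table1_rof.tsv",
                                                package = "rsnvar")) {
  tab <- read_tsv(path)
  need <- c("patient", "network", "rof_t1", "rof_t2", "delta_rof")
  if (nrow(tab) == 0L) stop_validation("empty ROF table")
  if (!all(need %in% names(tab)))
    stop_validation("ROF table needs columns: ", paste(need, collapse = ", "))
  tab$delta_recomputed <- delta_rof(tab$rof_t1, tab$rof_t2)
  printed <- ifelse(is.na(tab$delta_rof), 0, tab$delta_rof)
  match_cell <- abs(round(tab$delta_recomputed, 2) - round(printed, 2)) < 1e-9
  means <- vapply(split(tab, tab$patient), function(d)
    mean_abs_delta_rof(d$delta_recomputed, n_networks = nrow(d)), numeric(1))
  list(n_cells = nrow(tab), n_match = sum(match_cell),
       mismatches = tab[!match_cell,
                        c("patient", "network", "delta_rof",
                          "delta_recomputed")],
       mean_abs_delta_rof = means, recomputed = tab)
}
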