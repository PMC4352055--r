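#' Create a data-driven model-brain mapping from synthetic group data
#'
#' Runs the full mapping pipeline while holding at most one subject's 4D data
#' in memory: simulate subject -> first-level fit -> collect module betas;
#' then per module: group one-sample t map -> threshold with cluster-extent
#' filter -> grow a fixed-size ROI from the most significant voxel of the
#' largest cluster.
#'
#' @param task `"algebra"` or `"multitask"`.
#' @param n_subjects,n_trials Group size and trials per subject.
#' @param truth A [make_truth()] ground truth (also fixes the grid).
#' @param hrf,noise,tr As [simulate_group()].
#' @param p_thresh,min_extent,connectivity Cluster thresholding parameters
#'   (see [threshold_clusters()]); `min_extent` should be scaled to the
#'   grid's voxel volume.
#' @param target_size ROI size in voxels (default 100).
#' @param drift_order Drift order of the first-level design.
#' @param seed Master seed; subject s uses `seed + s`.
#' @param task_params Optional task parameter object.
#' @return List with `rois` (named list of [roi_mask()]), `maps` (named list
#'   of group [stat_map()]), `clusters` (named list of `cluster_set`) and
#'   `truth`.
#' @export
create_mapping <- function(task = "algebra", n_subjects = 18, n_trials = 8,
                           truth, hrf = hrf_spec(), noise = noise_model(),
                           tr = 2, p_thresh = 1e-7, min_extent = 50,
                           connectivity = 26, target_size = 100,
                           drift_order = 1, seed = 1, task_params = NULL) {
  betas <- list() # module -> list of subject beta vectors
  for (s in seq_len(n_subjects)) {
    set.seed(seed + s)
    session <- if (task == "algebra") {
      algebra_session(n_trials = n_trials,
                      params = task_params %||% algebra_params())
    } else {
      multitask_session(n_trials = n_trials,
                        params = task_params %||% multitask_params())
    }
    scans <- scan_grid(tr = tr, n_scans = ceiling(session$run_len / tr) + 1L)
    mult <- pmax(rnorm(length(truth$regions), 1, truth$subject_sd), 0)
    names(mult) <- names(truth$regions)
    run <- simulate_subject_run(session, truth, hrf, scans, noise,
                                multipliers = mult)
    design <- build_design_matrix(session$trace, hrf, scans,
                                  drift_order = drift_order)
    fit <- first_level_fit(run$bold, design)
    for (mod in fit$modules) {
      b <- fit$beta[, mod]
      b[is.na(b)] <- 0
      betas[[mod]] <- c(betas[[mod]], list(b))
    }
    rm(run, fit)
  }
  maps <- list()
  clusters <- list()
  rois <- list()
  for (mod in names(betas)) {
    maps[[mod]] <- group_map(betas[[mod]], truth$grid)
    clusters[[mod]] <- threshold_clusters(maps[[mod]], p_thresh = p_thresh,
                                          min_extent = min_extent,
                                          connectivity = connectivity)
    if (!nrow(clusters[[mod]]$clusters)) next
    best <- which(clusters[[mod]]$labels == 1L) # label 1 = highest peak |t|
    rois[[mod]] <- grow_region(maps[[mod]], best, seed = "auto",
                               target_size = target_size,
                               connectivity = connectivity, module = mod)
  }
  list(rois = rois, maps = maps, clusters = clusters, truth = truth)
}

#' Workflow: simulate a synthetic dataset onto disk
#'
#' Writes per-subject 4D NIfTI volumes, events TSV, trace TSV, ground-truth
#' masks and a provenance JSON into `out_dir`.
#'
#' @param config A [load_config()] object (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written subject file stems.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  grid <- volume_grid()
  centers <- module_centers()
  if (cfg$task == "algebra") centers$aural <- NULL else
    centers$manual_left <- c(33, -18, 57)
  truth <- make_truth(grid, centers, radius_mm = cfg$radius_mm)
  noise <- noise_model(sigma = cfg$sigma, kind = cfg$noise_kind,
                       ar_rho = cfg$ar_rho)
  group <- simulate_group(task = cfg$task, n_subjects = cfg$n_subjects,
                          n_trials = cfg$n_trials, truth = truth,
                          hrf = cfg$hrf_spec, noise = noise, tr = cfg$tr,
                          seed = cfg$seed)
  stems <- character(0)
  for (s in seq_along(group)) {
    stem <- file.path(out_dir, sprintf("sub-%02d", s))
    write_volume(group[[s]]$bold, grid, paste0(stem, "_bold.nii.gz"))
    write_events(group[[s]]$events, paste0(stem, "_events.tsv"))
    write_trace(group[[s]]$trace, paste0(stem, "_trace.tsv"))
    stems <- c(stems, stem)
  }
  for (mod in names(truth$regions)) {
    write_roi(truth$regions[[mod]],
              file.path(out_dir, paste0("truth_", mod, ".nii.gz")))
  }
  write_provenance(out_dir, "simulate", inputs = list(),
                   params = cfg[c("task", "n_subjects", "n_trials", "sigma",
                                  "noise_kind", "tr", "radius_mm")],
                   seed = cfg$seed)
  invisible(stems)
}

#' Workflow: predicted BOLD curves and regressors from a trace
#'
#' @param trace_path Trace TSV.
#' @param events_path Events TSV.
#' @param config A [load_config()] object or YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, the curves file path.
#' @export
run_predict <- function(trace_path, events_path, config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trace <- read_trace(trace_path)
  events <- read_events(events_path)
  scans <- scan_grid(tr = cfg$tr,
                     n_scans = ceiling(trace_end(trace) / cfg$tr) + 1L)
  curves <- predict_module_curves(trace, events, window = cfg$window,
                                  scans = scans, hrf = cfg$hrf_spec)
  path <- file.path(out_dir, "predicted_curves.tsv")
  write_curves(curves, path)
  design <- build_design_matrix(trace, cfg$hrf_spec, scans,
                                drift_order = cfg$drift_order)
  write.table(data.frame(scan = seq_len(nrow(design)) - 1L, design),
              file.path(out_dir, "regressors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, "predict",
                   inputs = list(trace = trace_path, events = events_path),
                   params = cfg[c("tr", "window", "drift_order")],
                   seed = cfg$seed)
  invisible(path)
}

#' Workflow: create a mapping from 4D data + traces on disk
#'
#' Reads per-subject BOLD/trace pairs, fits first levels, builds per-module
#' group maps, thresholds them and grows ROIs; writes stat maps, cluster
#' labels and reports, ROI masks with sidecars, and provenance.
#'
#' @param bold_paths,trace_paths Equal-length vectors of per-subject files.
#' @param config A [load_config()] object or YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, the named list of [roi_mask()] objects written.
#' @export
run_map <- function(bold_paths, trace_paths, config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  stopifnot(length(bold_paths) == length(trace_paths))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  betas <- list()
  grid <- NULL
  for (s in seq_along(bold_paths)) {
    vol <- read_volume(bold_paths[s])
    if (is.null(grid)) grid <- vol$grid else
      check_same_grid(grid, vol$grid, "subject volumes")
    trace <- read_trace(trace_paths[s])
    scans <- scan_grid(tr = cfg$tr, n_scans = dim(vol$data)[4])
    design <- build_design_matrix(trace, cfg$hrf_spec, scans,
                                  drift_order = cfg$drift_order)
    fit <- first_level_fit(vol$data, design)
    for (mod in fit$modules) {
      b <- fit$beta[, mod]
      b[is.na(b)] <- 0
      betas[[mod]] <- c(betas[[mod]], list(b))
    }
  }
  rois <- list()
  for (mod in names(betas)) {
    map <- group_map(betas[[mod]], grid)
    write_volume(array(map$t, dim = grid$dims), grid,
                 file.path(out_dir, paste0("group_t_", mod, ".nii.gz")))
    cl <- threshold_clusters(map, p_thresh = cfg$p_thresh,
                             min_extent = cfg$min_extent,
                             connectivity = cfg$connectivity)
    write_volume(cl$labels, grid,
                 file.path(out_dir, paste0("clusters_", mod, ".nii.gz")),
                 datatype = "int32")
    write_cluster_report(cl, file.path(out_dir,
                                       paste0("clusters_", mod, ".tsv")))
    if (!nrow(cl$clusters)) next
    roi <- grow_region(map, which(cl$labels == 1L), seed = "auto",
                       target_size = cfg$target_size,
                       connectivity = cfg$connectivity, module = mod)
    write_roi(roi, file.path(out_dir, paste0("roi_", mod, ".nii.gz")))
    rois[[mod]] <- roi
  }
  write_provenance(out_dir, "map",
                   inputs = list(bold = bold_paths, traces = trace_paths),
                   params = cfg[c("p_thresh", "min_extent", "target_size",
                                  "connectivity", "tr", "drift_order")],
                   seed = cfg$seed)
  invisible(rois)
}

#' Workflow: evaluate model predictions against ROI data
#'
#' Extracts event-locked percent-change curves per subject and ROI, averages
#' them, and writes fit reports (JSON and TSV) against the model's predicted
#' curves.
#'
#' @param bold_paths,events_paths Per-subject files (equal length).
#' @param roi_paths ROI NIfTI masks (module label read from the sidecar).
#' @param curves_path Model curves TSV from [run_predict()].
#' @param config A [load_config()] object or YAML path.
#' @param out_dir Output directory.
#' @return Invisibly, the list of [fit_report()]s.
#' @export
run_evaluate <- function(bold_paths, events_paths, roi_paths, curves_path,
                         config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rois <- lapply(roi_paths, read_roi)
  model_curves <- read_curves(curves_path)
  # one pass over subjects: validate grids, then extract every ROI's curves
  all_curves <- lapply(rois, function(r) vector("list", length(bold_paths)))
  for (s in seq_along(bold_paths)) {
    vol <- read_volume(bold_paths[s])
    for (roi in rois) check_same_grid(vol$grid, roi$grid, "data and ROI")
    events <- read_events(events_paths[s])
    scans <- scan_grid(tr = cfg$tr, n_scans = dim(vol$data)[4])
    for (r in seq_along(rois)) {
      tc <- extract_roi_timecourse(vol$data, rois[[r]])
      all_curves[[r]][[s]] <- event_locked_average(tc, events, cfg$window,
                                                   scans)
    }
  }
  reports <- list()
  for (r in seq_along(rois)) {
    roi <- rois[[r]]
    mod <- roi$module
    if (!mod %in% names(model_curves)) next
    subj_curves <- all_curves[[r]]
    common <- Reduce(intersect, lapply(subj_curves, colnames))
    if (!length(common)) {
      warning("no condition common to all subjects for ROI ", mod,
              "; skipped", call. = FALSE)
      next
    }
    subj_curves <- lapply(subj_curves, function(m) m[, common, drop = FALSE])
    agg <- Reduce(`+`, subj_curves) / length(subj_curves)
    mc <- model_curves[[mod]]
    if (is.null(dim(mc))) mc <- matrix(mc, ncol = 1, dimnames = list(NULL, "all"))
    reports[[mod]] <- fit_report(mc, agg, subj_curves, module = mod)
  }
  tab <- fit_table(reports)
  write.table(tab, file.path(out_dir, "fit_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(reports, unclass),
                       file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_provenance(out_dir, "evaluate",
                   inputs = list(bold = bold_paths, rois = roi_paths,
                                 curves = curves_path),
                   params = cfg[c("tr", "window")], seed = cfg$seed)
  invisible(reports)
}
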