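#' Write / read a volume (3D or 4D) as NIfTI-1
#'
#' Volumes are written as float32 (or uint8/int32 for masks and labels) with
#' the grid's affine stored in the sform (code 2).
#'
#' @param data 3D or 4D array.
#' @param grid A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype `"float"`, `"uint8"` or `"int32"`.
#' @return `write_volume` returns `path` invisibly; `read_volume` a list
#'   with `data` (array) and `grid`.
#' @export
write_volume <- function(data, grid, path, datatype = "float") {
  if (!identical(as.integer(dim(data)[1:3]), grid$dims)) {
    stop("data dimensions do not match grid", call. = FALSE)
  }
  img <- RNifti::asNifti(data, datatype = datatype)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  aff <- structure(RNifti::xform(img), dim = c(4, 4))
  grid <- volume_grid(dims = dim(img)[1:3], affine = unclass(aff))
  list(data = array(as.numeric(img), dim = dim(img)), grid = grid)
}

#' Write / read an events table (`onset  duration  condition  rt  correct`)
#'
#' @param events Data frame with the five columns above.
#' @param path TSV path.
#' @return `write_events` returns `path` invisibly; `read_events` the frame.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed events file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("onset", "duration", "condition")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("events file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a cluster peak report (`label  peak_t  peak_x_mm ... extent`)
#'
#' @param clusters A `cluster_set` from [threshold_clusters()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- clusters$clusters[, c("label", "peak_t", "peak_x_mm", "peak_y_mm",
                              "peak_z_mm", "extent")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' The configuration collects the mapping and evaluation parameters
#' (voxelwise p threshold, cluster extent, ROI target size, connectivity,
#' averaging window, HRF parameters, scan timing, behavioral filter,
#' master seed) plus any file paths the workflows need.
#'
#' @param path YAML file.
#' @return A list of class `run_config` with defaults filled in.
#' @export
load_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(p_thresh = 1e-7, min_extent = 250, target_size = 100,
                   connectivity = 26, window = 18, tr = 2, drift_order = 1,
                   seed = 1, task = "algebra", n_subjects = 18, n_trials = 72,
                   sigma = 1, noise_kind = "white", ar_rho = 0.3,
                   radius_mm = 12, accuracy_cutoff = 0.85, rt_sd_cutoff = 2)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (!cfg$connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  if (cfg$p_thresh <= 0 || cfg$p_thresh >= 1) {
    stop("p_thresh must be in (0, 1)", call. = FALSE)
  }
  for (nm in grep("_path$", names(cfg), value = TRUE)) {
    if (!file.exists(cfg[[nm]])) {
      stop("configured file does not exist: ", nm, " = ", cfg[[nm]],
           call. = FALSE)
    }
  }
  hrf_args <- cfg$hrf %||% list()
  cfg$hrf_spec <- do.call(hrf_spec, hrf_args)
  class(cfg) <- "run_config"
  cfg
}

write_provenance <- function(dir, command, inputs, params, seed) {
  jsonlite::write_json(
    list(command = command, inputs = inputs, parameters = params, seed = seed,
         tool = paste0("cogmap ", as.character(utils::packageVersion("cogmap"))),
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, paste0(command, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
}
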