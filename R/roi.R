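#' Default module ROI centers (mm, MNI, left hemisphere)
#'
#' Center coordinates of the data-driven mapping used as defaults by the
#' synthetic generator (they parameterize ground truth only; no algorithm
#' reads them): intraparietal sulcus for the problem state, inferior frontal
#' sulcus for declarative memory, precentral gyrus for the manual module,
#' superior temporal gyrus for the aural module and middle occipital gyrus
#' for the visual module.
#'
#' @param mapping `"data_driven"` (default) or `"original"` (the
#'   literature-based mapping; its visual region sits in the fusiform gyrus).
#' @return Named list of xyz mm coordinates.
#' @export
module_centers <- function(mapping = c("data_driven", "original")) {
  mapping <- match.arg(mapping)
  if (mapping == "data_driven") {
    list(problem_state = c(-38, -50, 48),
         declarative = c(-46, 16, 26),
         manual_right = c(-33, -18, 57),
         aural = c(-58, -21, 4),
         visual = c(-30, -84, 15))
  } else {
    list(problem_state = c(-24, -67, 44),
         declarative = c(-43, 24, 25),
         manual_right = c(-42, -23, 54),
         aural = c(-48, -21, 7),
         visual = c(-43, -60, -16))
  }
}

#' ROI mask
#'
#' A connected set of voxels grown from a seed, with bookkeeping used by the
#' evaluation stage.
#'
#' @param grid A [volume_grid()].
#' @param voxels 1-based linear voxel indices.
#' @param seed Seed voxel index (must be a member).
#' @param module Optional module label.
#' @param hemisphere `"left"`, `"right"`, or `NULL` to infer from the
#'   center-of-mass x sign.
#' @return A list of class `roi_mask` with `grid`, `voxels`, `seed`,
#'   `module`, `hemisphere` and `center_of_mass` (mm).
#' @export
roi_mask <- function(grid, voxels, seed = voxels[1], module = NA_character_,
                     hemisphere = NULL) {
  voxels <- sort(unique(as.integer(voxels)))
  if (!length(voxels)) stop("empty ROI", call. = FALSE)
  if (!seed %in% voxels) stop("seed must be a member voxel", call. = FALSE)
  com <- colMeans(voxel_world(grid, voxels))
  if (is.null(hemisphere)) hemisphere <- if (com[1] < 0) "left" else "right"
  structure(list(grid = grid, voxels = voxels, seed = as.integer(seed),
                 module = module, hemisphere = hemisphere,
                 center_of_mass = com),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s (%s): %d voxels, center of mass %.1f, %.1f, %.1f mm\n",
              x$module, x$hemisphere, length(x$voxels),
              x$center_of_mass[1], x$center_of_mass[2], x$center_of_mass[3]))
  invisible(x)
}

#' Center of mass of an ROI
#'
#' Unweighted mean of the member voxels' world coordinates.
#'
#' @param roi A [roi_mask()].
#' @return Numeric xyz in mm.
#' @export
roi_center_of_mass <- function(roi) {
  if (!length(roi$voxels)) stop("empty ROI", call. = FALSE)
  colMeans(voxel_world(roi$grid, roi$voxels))
}

#' Grow a fixed-size ROI from a seed in a statistical map
#'
#' Implements seeded greedy region growing: starting from the seed (by
#' default the most significant suprathreshold voxel), iteratively add the
#' most significant suprathreshold voxel bordering the current region until
#' `target_size` voxels are selected or no bordering suprathreshold voxel
#' remains (in which case the shorter region is returned with a warning).
#'
#' @param map A [stat_map()].
#' @param supra_mask Suprathreshold voxels: logical vector/array or 1-based
#'   indices (e.g. one cluster from [threshold_clusters()]).
#' @param seed `"auto"` (voxel of max significance in `supra_mask`) or a
#'   voxel index inside `supra_mask`.
#' @param target_size Number of voxels to grow to (default 100).
#' @param connectivity Adjacency for "bordering": 6, 18 or 26 (default 26).
#' @param significance `"abs"` (max |t|, default) or `"signed"` (max t).
#' @param module Optional module label stored in the result.
#' @return A [roi_mask()].
#' @export
grow_region <- function(map, supra_mask, seed = "auto", target_size = 100,
                        connectivity = 26, significance = c("abs", "signed"),
                        module = NA_character_) {
  significance <- match.arg(significance)
  score <- if (significance == "abs") abs(map$t) else map$t
  supra <- if (is.logical(supra_mask) || is.array(supra_mask)) {
    which(as.logical(supra_mask))
  } else {
    as.integer(supra_mask)
  }
  if (!length(supra)) stop("suprathreshold mask is empty", call. = FALSE)
  if (identical(seed, "auto")) {
    seed <- supra[which.max(score[supra])]
  } else if (!seed %in% supra) {
    stop("seed voxel is not in the suprathreshold mask", call. = FALSE)
  }
  dims <- map$grid$dims
  offsets <- neighbor_offsets(connectivity)
  insupra <- logical(prod(dims))
  insupra[supra] <- TRUE
  selected <- logical(prod(dims))
  selected[seed] <- TRUE
  region <- seed
  frontier <- integer(0)
  add_frontier <- function(frontier, vox) {
    nb <- voxel_neighbors(vox, dims, offsets)
    union(frontier, nb[insupra[nb] & !selected[nb]])
  }
  frontier <- add_frontier(frontier, seed)
  while (length(region) < target_size && length(frontier)) {
    # max significance; ties by lowest linear index (deterministic)
    best <- frontier[order(-score[frontier], frontier)][1L]
    selected[best] <- TRUE
    region <- c(region, best)
    frontier <- setdiff(add_frontier(frontier, best), best)
  }
  if (length(region) < target_size) {
    warning(sprintf("region exhausted at %d of %d voxels", length(region),
                    target_size), call. = FALSE)
  }
  roi_mask(map$grid, region, seed = seed, module = module)
}

#' Restrict a suprathreshold mask to anatomical labels
#'
#' Intersects the growth domain with the voxels of an anatomical parcellation
#' carrying the given labels (applied before growing, so the region is
#' defined within the anatomical structure).
#'
#' @param supra_mask Logical vector/array or 1-based voxel indices.
#' @param label_image Integer array of anatomical labels on the same grid.
#' @param keep_labels Label values to keep.
#' @param grid Optional [volume_grid()] of `supra_mask` for the dimension
#'   check when `supra_mask` is an index vector.
#' @return Integer vector of surviving voxel indices.
#' @export
restrict_domain <- function(supra_mask, label_image, keep_labels, grid = NULL) {
  if (is.logical(supra_mask) || is.array(supra_mask)) {
    if (!is.null(dim(supra_mask)) &&
        !identical(dim(supra_mask), dim(label_image))) {
      stop("label image grid does not match mask grid", call. = FALSE)
    }
    supra <- which(as.logical(supra_mask))
  } else {
    if (!is.null(grid) && !identical(grid$dims, dim(label_image))) {
      stop("label image grid does not match mask grid", call. = FALSE)
    }
    supra <- as.integer(supra_mask)
  }
  out <- supra[label_image[supra] %in% keep_labels]
  if (!length(out)) {
    stop("no suprathreshold voxels carry label(s) ",
         paste(keep_labels, collapse = ", "), call. = FALSE)
  }
  out
}

#' Mirror an ROI across the midsagittal plane
#'
#' Maps each member voxel to the voxel nearest its world coordinate with x
#' negated (reflection about x = 0 mm in world space, robust to affines whose
#' midline falls between voxel columns) and flips the hemisphere label.
#' Reflected voxels falling outside the grid are dropped with a warning.
#'
#' @param roi A [roi_mask()].
#' @return The mirrored [roi_mask()].
#' @export
mirror_roi <- function(roi) {
  xyz <- voxel_world(roi$grid, roi$voxels)
  xyz[, 1] <- -xyz[, 1]
  idx <- world_voxel(roi$grid, xyz)
  dropped <- sum(is.na(idx))
  if (dropped) {
    warning(dropped, " reflected voxel(s) fell outside the grid and were dropped",
            call. = FALSE)
  }
  idx <- unique(idx[!is.na(idx)])
  if (!length(idx)) stop("mirrored ROI is empty", call. = FALSE)
  seed_m <- world_voxel(roi$grid,
                        voxel_world(roi$grid, roi$seed) * c(-1, 1, 1))
  if (is.na(seed_m) || !seed_m %in% idx) seed_m <- idx[1]
  roi_mask(roi$grid, idx, seed = seed_m, module = roi$module,
           hemisphere = if (roi$hemisphere == "left") "right" else "left")
}

#' Write / read an ROI as NIfTI (uint8) with a JSON sidecar
#'
#' The mask is written as a binary uint8 NIfTI volume; a sidecar JSON
#' (same path, extension `.json`) records module, hemisphere, seed voxel
#' (0-based triple), size and center of mass.
#'
#' @param roi A [roi_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_roi` returns `path` invisibly; `read_roi` a [roi_mask()].
#' @export
write_roi <- function(roi, path) {
  arr <- array(0L, dim = roi$grid$dims)
  arr[roi$voxels] <- 1L
  write_volume(arr, roi$grid, path, datatype = "uint8")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(module = roi$module, hemisphere = roi$hemisphere,
         seed_voxel = as.integer(idx_to_vox(roi$seed, roi$grid$dims)),
         size = length(roi$voxels),
         center_of_mass_mm = round(unname(roi$center_of_mass), 3)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  vol <- read_volume(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  voxels <- which(vol$data > 0.5)
  seed <- if (!is.null(meta$seed_voxel)) {
    vox_to_idx(matrix(unlist(meta$seed_voxel), ncol = 3), vol$grid$dims)
  } else {
    voxels[1]
  }
  roi_mask(vol$grid, voxels, seed = seed,
           module = if (is.null(meta$module)) NA_character_ else meta$module,
           hemisphere = meta$hemisphere)
}
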