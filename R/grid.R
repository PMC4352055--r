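#' Volume grid: voxel dimensions plus world transform
#'
#' Describes the 3D sampling grid of all volumetric objects. The world
#' transform maps 0-based voxel indices to mm coordinates in MNI convention
#' (axis 1 is left--right with negative x on the left).
#'
#' @param dims Integer vector `(nx, ny, nz)`.
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param origin World coordinate (mm) of voxel `(0, 0, 0)`. The default
#'   centers the default grid on MNI-like coordinates.
#' @param affine Full 4x4 voxel-to-world affine; overrides
#'   `voxel_size`/`origin` when given.
#' @return A list of class `volume_grid` with `dims` and `affine`.
#' @export
volume_grid <- function(dims = c(40L, 48L, 40L), voxel_size = 4,
                        origin = c(-78, -112, -50), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L)) {
    stop("dims must be three positive integers", call. = FALSE)
  }
  if (is.null(affine)) {
    voxel_size <- rep(voxel_size, length.out = 3)
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible", call. = FALSE)
  structure(list(dims = dims, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid>", paste(x$dims, collapse = " x "), "voxels, voxel size",
      paste(sprintf("%.3g", abs(diag(x$affine)[1:3])), collapse = " x "),
      "mm\n")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) < 1e-6
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(what, " are on different grids", call. = FALSE)
  invisible(TRUE)
}

# linear index (1-based) <-> 0-based voxel index triple
idx_to_vox <- function(idx, dims) {
  idx0 <- idx - 1L
  cbind(i = idx0 %% dims[1],
        j = (idx0 %/% dims[1]) %% dims[2],
        k = idx0 %/% (dims[1] * dims[2]))
}

vox_to_idx <- function(vox, dims) {
  as.integer(vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]) + 1L)
}

#' World coordinates of voxels
#'
#' @param grid A [volume_grid()].
#' @param idx 1-based linear voxel indices.
#' @return Matrix of mm coordinates (one row per voxel).
#' @export
voxel_world <- function(grid, idx) {
  vox <- idx_to_vox(idx, grid$dims)
  xyz <- cbind(vox, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Nearest voxel of world coordinates
#'
#' @param grid A [volume_grid()].
#' @param xyz Matrix of mm coordinates (one row per point).
#' @return 1-based linear voxel indices; `NA` for points outside the grid.
#' @export
world_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  vox <- round(cbind(xyz, 1) %*% t(solve(grid$affine)))[, 1:3, drop = FALSE]
  ok <- vox[, 1] >= 0 & vox[, 1] < grid$dims[1] &
    vox[, 2] >= 0 & vox[, 2] < grid$dims[2] &
    vox[, 3] >= 0 & vox[, 3] < grid$dims[3]
  out <- rep(NA_integer_, nrow(vox))
  out[ok] <- vox_to_idx(vox[ok, , drop = FALSE], grid$dims)
  out
}

# neighbor index offsets for 6/18/26-connectivity
neighbor_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) {
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  }
  d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(d))
  keep <- ord > 0 & switch(as.character(connectivity),
                           "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  d[keep, , drop = FALSE]
}

# neighbors of 1-based linear indices within the grid (vectorized over offsets)
voxel_neighbors <- function(idx, dims, offsets) {
  vox <- idx_to_vox(idx, dims)
  out <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(vox, 2, offsets[r, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
      nb[, 2] >= 0 & nb[, 2] < dims[2] &
      nb[, 3] >= 0 & nb[, 3] < dims[3]
    out <- c(out, vox_to_idx(nb[ok, , drop = FALSE], dims))
  }
  unique(out)
}

# connected components of a set of voxels; returns list of index vectors
connected_components <- function(idx, dims, connectivity = 26) {
  offsets <- neighbor_offsets(connectivity)
  inset <- logical(prod(dims))
  inset[idx] <- TRUE
  seen <- logical(prod(dims))
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      comp <- c(comp, cur)
      nb <- voxel_neighbors(cur, dims, offsets)
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
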