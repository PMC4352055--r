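#' Build the model-based design matrix for one run
#'
#' One convolved-and-scan-sampled regressor per module present in the trace,
#' mean-centered and scaled to unit standard deviation (so betas are
#' expressed in signal units per unit-SD predictor and are comparable across
#' subjects whose sessions differ), polynomial drift columns up to
#' `drift_order`, and an intercept column last.
#'
#' @param trace Run-level [demand_trace()].
#' @param hrf An [hrf_spec()].
#' @param scans A [scan_grid()].
#' @param drift_order Polynomial drift order (default 1; 0 for none).
#' @return Numeric matrix `scans x columns` with column names; module columns
#'   carry the attribute `modules`.
#' @export
build_design_matrix <- function(trace, hrf = hrf_spec(), scans,
                                drift_order = 1) {
  kern <- hrf_kernel(hrf)
  total_len <- max(trace_end(trace),
                   scans$run_onset + (scans$n_scans - 1L) * scans$tr)
  cols <- list()
  for (mod in intersect(module_names(), names(trace$intervals))) {
    bc <- demand_to_boxcar(trace, mod, dt = hrf$dt, total_len = total_len)
    x <- convolve_predict(bc, kern, scans)
    if (all(abs(x) < 1e-12)) {
      warning("module ", mod, " has empty demand; regressor excluded",
              call. = FALSE)
      next
    }
    cols[[mod]] <- (x - mean(x)) / sd(x)
  }
  if (!length(cols)) stop("no nonempty module regressors", call. = FALSE)
  X <- do.call(cbind, cols)
  modules <- colnames(X)
  if (drift_order >= 1) {
    dr <- poly(seq_len(scans$n_scans), degree = drift_order)
    colnames(dr) <- paste0("drift", seq_len(drift_order))
    X <- cbind(X, dr)
  }
  X <- cbind(X, intercept = 1)
  if (qr(X)$rank < ncol(X)) {
    cc <- cor(X[, modules, drop = FALSE])
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop("design matrix is rank deficient; most collinear module pair: ",
         modules[worst[1]], " / ", modules[worst[2]],
         sprintf(" (r = %.3f)", cc[worst[1], worst[2]]), call. = FALSE)
  }
  attr(X, "modules") <- modules
  X
}

as_scan_matrix <- function(bold) {
  # 4D array (x,y,z,scan) -> scans x voxels matrix
  if (is.matrix(bold)) return(bold)
  d <- dim(bold)
  if (length(d) != 4L) stop("bold data must be a 4D array or scans x voxels matrix",
                            call. = FALSE)
  t(matrix(bold, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Voxelwise ordinary least squares for one subject
#'
#' Fits `y = X b + e` independently at every in-mask voxel and returns betas,
#' residual variance and t statistics (`t = b / SE(b)`, `df = scans - columns`).
#' Voxels with zero variance are excluded from the mask.
#'
#' @param bold 4D array `(x, y, z, scan)` or a `scans x voxels` matrix.
#' @param design Design matrix from [build_design_matrix()].
#' @param mask Optional logical vector/array of in-brain voxels; default is
#'   all voxels with nonzero variance.
#' @return List with `beta`, `t` (voxels x columns matrices, `NA` outside the
#'   mask), `sigma2`, `mask`, `df` and `modules`.
#' @export
first_level_fit <- function(bold, design, mask = NULL) {
  Y <- as_scan_matrix(bold)
  if (nrow(Y) != nrow(design)) {
    stop("data has ", nrow(Y), " scans but design has ", nrow(design), " rows",
         call. = FALSE)
  }
  nvox <- ncol(Y)
  v <- matrixStats_colVars(Y)
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  mask <- as.logical(mask) & v > 1e-12
  df <- nrow(design) - ncol(design)
  if (df <= 0) stop("need more scans than design columns", call. = FALSE)
  XtXi <- solve(crossprod(design))
  B <- matrix(NA_real_, nvox, ncol(design),
              dimnames = list(NULL, colnames(design)))
  Tm <- B
  sigma2 <- rep(NA_real_, nvox)
  Ym <- Y[, mask, drop = FALSE]
  Bm <- XtXi %*% crossprod(design, Ym)
  res <- Ym - design %*% Bm
  s2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtXi), s2))
  B[mask, ] <- t(Bm)
  Tm[mask, ] <- t(Bm / se)
  sigma2[mask] <- s2
  list(beta = B, t = Tm, sigma2 = sigma2, mask = mask, df = df,
       modules = attr(design, "modules"))
}

# column variances without matrixStats
matrixStats_colVars <- function(Y) {
  n <- nrow(Y)
  if (n < 2L) return(rep(0, ncol(Y)))
  mu <- colMeans(Y)
  (colSums(Y^2) - n * mu^2) / (n - 1L)
}

#' Statistical map on a volume grid
#'
#' @param grid A [volume_grid()].
#' @param t Numeric vector/array of t values (length = voxels).
#' @param df Degrees of freedom.
#' @param p Optional p values; default two-sided from `t` and `df`.
#' @return A list of class `stat_map` with `grid`, `t`, `p`, `df`.
#' @export
stat_map <- function(grid, t, df, p = NULL) {
  t <- as.numeric(t)
  if (length(t) != n_voxels(grid)) {
    stop("t map length does not match grid", call. = FALSE)
  }
  if (is.null(p)) p <- pmax(2 * pt(-abs(t), df), 1e-300)
  structure(list(grid = grid, t = t, p = p, df = df), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map>", paste(x$grid$dims, collapse = " x "),
      sprintf("voxels, df = %s, max |t| = %.2f\n", x$df,
              max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

#' Group-level one-sample t map across subject beta maps
#'
#' @param subject_betas List (length >= 3) of per-voxel beta vectors/arrays,
#'   one per subject, all on `grid`.
#' @param grid The common [volume_grid()].
#' @param t_cap Cap on |t| for zero-variance voxels (default 1e6).
#' @return A [stat_map()] with `df = n_subjects - 1` and two-sided p.
#' @export
group_map <- function(subject_betas, grid, t_cap = 1e6) {
  n <- length(subject_betas)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  lens <- vapply(subject_betas, length, 0L)
  if (any(lens != n_voxels(grid))) {
    stop("subject beta maps are on different grids", call. = FALSE)
  }
  B <- vapply(subject_betas, as.numeric, numeric(lens[1]))
  mu <- rowMeans(B)
  s <- sqrt(rowSums((B - mu)^2) / (n - 1L))
  t <- mu / (s / sqrt(n))
  t[s == 0 & mu != 0] <- sign(mu[s == 0 & mu != 0]) * t_cap
  t[s == 0 & mu == 0] <- 0
  t[is.na(t)] <- 0
  t <- pmin(pmax(t, -t_cap), t_cap)
  stat_map(grid, t, df = n - 1L)
}

#' Threshold a stat map and filter clusters by extent
#'
#' Voxels with `p < p_thresh` form connected components under the chosen
#' connectivity; components smaller than `min_extent` voxels are removed and
#' the survivors are labeled 1, 2, ... by descending peak |t|.
#'
#' @param map A [stat_map()].
#' @param p_thresh Voxelwise threshold (default 1e-7, uncorrected).
#' @param min_extent Minimum cluster size in voxels (default 250).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of class `cluster_set`: `labels` (integer array, 0 =
#'   background), `clusters` (data.frame `label, extent, peak_t, peak_x_mm,
#'   peak_y_mm, peak_z_mm`), plus the thresholding parameters.
#' @export
threshold_clusters <- function(map, p_thresh = 1e-7, min_extent = 250,
                               connectivity = 26) {
  supra <- which(map$p < p_thresh)
  comps <- connected_components(supra, map$grid$dims, connectivity)
  comps <- comps[vapply(comps, length, 0L) >= min_extent]
  peak <- vapply(comps, function(ix) max(abs(map$t[ix])), numeric(1))
  ord <- order(peak, decreasing = TRUE)
  comps <- comps[ord]
  labels <- array(0L, dim = map$grid$dims)
  rows <- lapply(seq_along(comps), function(l) {
    ix <- comps[[l]]
    labels[ix] <<- l
    pk <- ix[which.max(abs(map$t[ix]))]
    xyz <- voxel_world(map$grid, pk)
    data.frame(label = l, extent = length(ix), peak_t = map$t[pk],
               peak_x_mm = xyz[1], peak_y_mm = xyz[2], peak_z_mm = xyz[3])
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), extent = integer(0), peak_t = numeric(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0))
  structure(list(labels = labels, clusters = clusters, grid = map$grid,
                 p_thresh = p_thresh, min_extent = min_extent,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' Exclusive-variance (dissociation) map between two regressors
#'
#' For each subject and voxel, computes the difference of squared semipartial
#' correlations: the variance uniquely explained by regressor A (given all
#' other columns) minus that of regressor B. The per-subject differences are
#' then entered into a group one-sample t map; the positive tail marks
#' A-exclusive regions.
#'
#' @param bold_list List of per-subject 4D arrays (or scan x voxel matrices).
#' @param design_list List of per-subject design matrices (same columns).
#' @param regA,regB Column labels to dissociate.
#' @param grid The common [volume_grid()].
#' @return A [stat_map()] of the group t over per-subject sr2 differences.
#' @export
exclusive_contrast <- function(bold_list, design_list, regA, regB, grid) {
  stopifnot(length(bold_list) == length(design_list))
  diffs <- vector("list", length(bold_list))
  for (s in seq_along(bold_list)) {
    X <- design_list[[s]]
    if (!all(c(regA, regB) %in% colnames(X))) {
      stop("regressors ", regA, " and ", regB, " must both be in the design",
           call. = FALSE)
    }
    r_ab <- cor(X[, regA], X[, regB])
    if (abs(r_ab) > 0.99) {
      stop(sprintf("regressors %s and %s are collinear (r = %.3f)",
                   regA, regB, r_ab), call. = FALSE)
    }
    Y <- as_scan_matrix(bold_list[[s]])
    Yc <- sweep(Y, 2, colMeans(Y))
    tss <- colSums(Yc^2)
    tss[tss == 0] <- NA_real_
    rss <- function(Xs) {
      Q <- qr.Q(qr(Xs))
      colSums(Y^2) - colSums((crossprod(Q, Y))^2)
    }
    # sr2_A - sr2_B = (RSS_{-A} - RSS_{-B}) / TSS
    d <- (rss(X[, setdiff(colnames(X), regA), drop = FALSE]) -
            rss(X[, setdiff(colnames(X), regB), drop = FALSE])) / tss
    d[is.na(d)] <- 0
    diffs[[s]] <- d
  }
  group_map(diffs, grid)
}
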