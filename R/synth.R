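#' Noise model for synthetic fMRI
#'
#' @param sigma Noise standard deviation in signal units (>= 0).
#' @param kind `"white"` or `"ar1"`.
#' @param ar_rho Lag-1 autocorrelation for `"ar1"` (|rho| < 1); the marginal
#'   SD is kept at `sigma`.
#' @param drift_amp Amplitude of a linear drift added to every voxel
#'   (peak-to-peak, signal units; default 0).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 1, kind = c("white", "ar1"), ar_rho = 0.3,
                        drift_amp = 0) {
  kind <- match.arg(kind)
  if (sigma < 0 || abs(ar_rho) >= 1) {
    stop("need sigma >= 0 and |ar_rho| < 1", call. = FALSE)
  }
  structure(list(sigma = sigma, kind = kind, ar_rho = ar_rho,
                 drift_amp = drift_amp), class = "noise_model")
}

draw_noise <- function(noise, n_scans, n_vox) {
  if (noise$sigma == 0) return(matrix(0, n_scans, n_vox))
  e <- matrix(rnorm(n_scans * n_vox), n_scans, n_vox)
  if (noise$kind == "ar1" && noise$ar_rho != 0) {
    e <- stats::filter(e * sqrt(1 - noise$ar_rho^2), noise$ar_rho,
                       method = "recursive")
    e <- matrix(as.numeric(e), n_scans, n_vox)
  }
  noise$sigma * e
}

#' Ground-truth module regions for the synthetic generator
#'
#' Builds one spherical region per module around the given centers
#' (defaults: the data-driven mapping's left-hemisphere centers) and errors
#' if any two spheres overlap.
#'
#' @param grid A [volume_grid()].
#' @param centers Named list module -> xyz mm (default [module_centers()]).
#' @param radius_mm Sphere radius in mm (default 12, giving regions slightly
#'   above the 100-voxel ROI target size on the default 4 mm grid).
#' @param amplitude Named or scalar response amplitude per unit-SD regressor
#'   (signal units; default 1).
#' @param subject_sd SD of the per-subject amplitude multiplier
#'   (mean 1; default 0.2).
#' @return A list of class `ground_truth` with `regions` (named list of
#'   [roi_mask()]), `amplitude`, `subject_sd`.
#' @export
make_truth <- function(grid, centers = module_centers(), radius_mm = 12,
                       amplitude = 1, subject_sd = 0.2) {
  check_module(names(centers))
  all_xyz <- voxel_world(grid, seq_len(n_voxels(grid)))
  regions <- list()
  for (mod in names(centers)) {
    ctr <- centers[[mod]]
    inside <- world_voxel(grid, matrix(ctr, ncol = 3))
    if (is.na(inside)) stop("center of ", mod, " lies outside the grid",
                            call. = FALSE)
    d2 <- (all_xyz[, 1] - ctr[1])^2 + (all_xyz[, 2] - ctr[2])^2 +
      (all_xyz[, 3] - ctr[3])^2
    vox <- which(d2 <= radius_mm^2)
    if (!length(vox)) vox <- inside # radius below voxel size: single voxel
    regions[[mod]] <- roi_mask(grid, vox, seed = inside, module = mod)
  }
  mods <- names(regions)
  for (a in seq_along(mods)) {
    for (b in seq_len(a - 1L)) {
      if (length(intersect(regions[[a]]$voxels, regions[[b]]$voxels))) {
        stop("ground-truth regions overlap: ", mods[b], " / ", mods[a],
             call. = FALSE)
      }
    }
  }
  amplitude <- if (length(amplitude) == 1L) {
    setNames(rep(amplitude, length(mods)), mods)
  } else {
    amplitude[mods]
  }
  if (any(amplitude < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  structure(list(regions = regions, amplitude = amplitude,
                 subject_sd = subject_sd, grid = grid, radius_mm = radius_mm),
            class = "ground_truth")
}

#' Simulate one subject's 4D run from a demand trace
#'
#' Generative direction of the forward model: each ground-truth voxel's
#' series is `baseline + multiplier * amplitude * regressor + drift + noise`,
#' where the regressor is the module's convolved demand sampled at scan times
#' and scaled to unit SD (so `amplitude / sigma` is the per-voxel SNR).
#' Out-of-region voxels get baseline + drift + noise only.
#'
#' @param session List with `trace` and `events` (from [algebra_session()],
#'   [multitask_session()], or hand-built).
#' @param truth A [make_truth()] object.
#' @param hrf An [hrf_spec()].
#' @param scans A [scan_grid()] covering the run.
#' @param noise A [noise_model()].
#' @param baseline Baseline signal level (default 100, so unit amplitudes are
#'   ~1% signal change).
#' @param multipliers Named per-module amplitude multipliers for this subject
#'   (default all 1).
#' @return List with `bold` (4D array), `events`, `regressors`
#'   (scans x modules, unit SD), `scans`, `grid`.
#' @export
simulate_subject_run <- function(session, truth, hrf = hrf_spec(), scans,
                                 noise = noise_model(), baseline = 100,
                                 multipliers = NULL) {
  grid <- truth$grid
  kern <- hrf_kernel(hrf)
  total_len <- max(trace_end(session$trace),
                   scans$run_onset + (scans$n_scans - 1L) * scans$tr)
  mods <- intersect(names(truth$regions), names(session$trace$intervals))
  regressors <- vapply(mods, function(mod) {
    bc <- demand_to_boxcar(session$trace, mod, dt = hrf$dt,
                           total_len = total_len)
    x <- convolve_predict(bc, kern, scans)
    s <- sd(x)
    if (s > 0) (x - mean(x)) / s else x
  }, numeric(scans$n_scans))
  regressors <- matrix(regressors, nrow = scans$n_scans,
                       dimnames = list(NULL, mods))
  if (is.null(multipliers)) multipliers <- setNames(rep(1, length(mods)), mods)
  nv <- n_voxels(grid)
  Y <- draw_noise(noise, scans$n_scans, nv) + baseline
  if (noise$drift_amp != 0) {
    dr <- noise$drift_amp * (seq_len(scans$n_scans) / scans$n_scans - 0.5)
    Y <- Y + dr
  }
  for (mod in mods) {
    vox <- truth$regions[[mod]]$voxels
    sig <- multipliers[[mod]] * truth$amplitude[[mod]] * regressors[, mod]
    Y[, vox] <- Y[, vox] + sig
  }
  list(bold = array(t(Y), dim = c(grid$dims, scans$n_scans)),
       events = session$events, regressors = regressors,
       scans = scans, grid = grid)
}

#' Simulate a group of subjects with shared ground truth
#'
#' Each subject gets a fresh task session (new traces), a subject-specific
#' amplitude multiplier (normal, mean 1, SD `truth$subject_sd`, truncated at
#' 0) shared across that subject's modules, and independent noise.
#'
#' @param task `"algebra"` or `"multitask"`.
#' @param n_subjects Number of subjects (default 18; >= 3).
#' @param n_trials Trials per subject (default 72: 18 per condition for
#'   algebra, 12 for multitask).
#' @param truth A [make_truth()] object.
#' @param hrf,noise,baseline As [simulate_subject_run()].
#' @param tr Repetition time (default 2 s).
#' @param seed Optional master seed; subject `s` derives sub-seed
#'   `seed + s` so datasets are reproducible. For large runs prefer
#'   [create_mapping()], which generates and fits one subject at a time.
#' @param task_params Optional [algebra_params()] / [multitask_params()].
#' @return List of per-subject lists as returned by [simulate_subject_run()],
#'   with attribute `truth`.
#' @export
simulate_group <- function(task = c("algebra", "multitask"), n_subjects = 18,
                           n_trials = 72, truth, hrf = hrf_spec(),
                           noise = noise_model(), baseline = 100, tr = 2,
                           seed = NULL, task_params = NULL) {
  task <- match.arg(task)
  if (n_subjects < 3L) stop("need n_subjects >= 3", call. = FALSE)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    if (!is.null(seed)) set.seed(seed + s)
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
    subjects[[s]] <- simulate_subject_run(session, truth, hrf, scans, noise,
                                          baseline, multipliers = mult)
    subjects[[s]]$trace <- session$trace
    subjects[[s]]$multipliers <- mult
  }
  attr(subjects, "truth") <- truth
  subjects
}

#' Toy statistical map with blobs of exact voxel counts
#'
#' Builds a [stat_map()] whose suprathreshold set consists of the requested
#' blobs: for each blob the `size` voxels nearest its center (a connected,
#' roughly spherical set) get t values decaying linearly from `peak_t` at the
#' center to `t_floor` at the rim; background voxels draw null t values.
#'
#' @param grid A [volume_grid()].
#' @param blobs List of lists with `center` (mm), `size` (voxels), and
#'   optional `peak_t` (default 25).
#' @param df Degrees of freedom of the map (default 17).
#' @param t_floor Rim t value; must itself be suprathreshold at the intended
#'   threshold (default 12).
#' @return A [stat_map()] with attribute `blob_voxels` (list of index sets).
#' @export
make_toy_statmap <- function(grid, blobs = list(), df = 17, t_floor = 12) {
  t <- rnorm(n_voxels(grid))
  all_xyz <- voxel_world(grid, seq_len(n_voxels(grid)))
  used <- integer(0)
  blob_voxels <- list()
  for (b in blobs) {
    if (b$size < 1) stop("blob sizes must be >= 1", call. = FALSE)
    peak_t <- b$peak_t %||% 25
    d2 <- (all_xyz[, 1] - b$center[1])^2 + (all_xyz[, 2] - b$center[2])^2 +
      (all_xyz[, 3] - b$center[3])^2
    vox <- order(d2)[seq_len(b$size)]
    if (length(intersect(vox, used))) {
      stop("blobs collide; move centers apart", call. = FALSE)
    }
    used <- c(used, vox)
    t[vox] <- peak_t - (peak_t - t_floor) * rank(d2[vox], ties.method = "first") /
      max(b$size, 2L)
    blob_voxels[[length(blob_voxels) + 1L]] <- sort(vox)
  }
  out <- stat_map(grid, t, df = df)
  attr(out, "blob_voxels") <- blob_voxels
  out
}

#' Dice overlap of two voxel sets
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical sets.
#'
#' @param a,b [roi_mask()] objects or integer voxel index vectors.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  va <- if (inherits(a, "roi_mask")) a$voxels else as.integer(a)
  vb <- if (inherits(b, "roi_mask")) b$voxels else as.integer(b)
  2 * length(intersect(va, vb)) / (length(va) + length(vb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
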