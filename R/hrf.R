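#' Double-gamma hemodynamic response specification
#'
#' The canonical HRF used throughout: the difference of two gamma densities,
#' a positive response peaking around 5 s and a later undershoot. Defaults
#' follow the conventional parameterization (shapes 6 and 16, unit rates,
#' undershoot ratio 1/6, 32 s support).
#'
#' @param peak_shape,peak_rate Shape and rate (1/s) of the response gamma.
#' @param undershoot_shape,undershoot_rate Shape and rate of the undershoot.
#' @param undershoot_ratio Weight of the undershoot term (default 1/6).
#' @param support Kernel length in seconds (default 32).
#' @param dt Sampling resolution in seconds (default 0.1).
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_shape = 6, undershoot_shape = 16,
                     peak_rate = 1, undershoot_rate = 1,
                     undershoot_ratio = 1 / 6, support = 32, dt = 0.1) {
  p <- as.list(environment())
  if (any(c(p$peak_shape, p$undershoot_shape, p$peak_rate,
            p$undershoot_rate) <= 0)) {
    stop("gamma shapes and rates must be > 0", call. = FALSE)
  }
  if (p$support <= 0 || p$dt <= 0 || p$dt > p$support) {
    stop("need support > 0 and 0 < dt <= support", call. = FALSE)
  }
  class(p) <- "hrf_spec"
  p
}

#' Sample the HRF kernel
#'
#' `h(t) = g(t; peak) - ratio * g(t; undershoot)` with `g` the gamma density,
#' sampled on `[0, support]` at resolution `dt`. The kernel is returned
#' unnormalized; convolution scales by `dt` so predictions approximate the
#' continuous convolution integral.
#'
#' @param spec An [hrf_spec()].
#' @return Numeric vector with attribute `dt`; element `k` is `h((k-1)*dt)`.
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  t <- seq(0, spec$support, by = spec$dt)
  h <- dgamma(t, shape = spec$peak_shape, rate = spec$peak_rate) -
    spec$undershoot_ratio *
      dgamma(t, shape = spec$undershoot_shape, rate = spec$undershoot_rate)
  attr(h, "dt") <- spec$dt
  h
}

#' Scan grid of an fMRI run
#'
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes.
#' @param run_onset Time of the first scan in seconds (default 0).
#' @return A list of class `scan_grid`. Scan `k` (1-based) samples time
#'   `run_onset + (k-1)*tr`.
#' @export
scan_grid <- function(tr = 2, n_scans, run_onset = 0) {
  if (tr <= 0 || n_scans < 1) stop("need tr > 0 and n_scans >= 1", call. = FALSE)
  structure(list(tr = tr, n_scans = as.integer(n_scans),
                 run_onset = run_onset), class = "scan_grid")
}

scan_times <- function(scans) {
  scans$run_onset + (seq_len(scans$n_scans) - 1L) * scans$tr
}

#' Sample a module's 0--1 demand function on a regular grid
#'
#' Sample `k` (1-based) represents the grid cell `[(k-1)*dt, k*dt)` and takes
#' the fraction of that cell covered by the module's half-open intervals
#' `[onset, offset)`. For intervals aligned to the grid this is exactly the
#' 0/1 indicator; for unaligned interval edges the fractional value keeps the
#' sampled demand mass exact, so convolved predictions are stable under `dt`
#' refinement.
#'
#' @param trace A [demand_trace()].
#' @param module Module label.
#' @param dt Grid resolution in seconds.
#' @param total_len Length of the sampled function in seconds; must cover all
#'   of the module's intervals.
#' @return Numeric vector in \[0, 1\] of length `floor(total_len/dt) + 1`
#'   with attribute `dt`.
#' @export
demand_to_boxcar <- function(trace, module, dt = 0.1, total_len = NULL) {
  check_module(module)
  m <- trace$intervals[[module]]
  if (is.null(m)) m <- matrix(numeric(0), ncol = 2)
  if (is.null(total_len)) total_len <- trace_end(trace)
  if (nrow(m) && max(m[, 2]) > total_len + 1e-9) {
    bad <- m[which.max(m[, 2]), ]
    stop(sprintf("interval [%.3f, %.3f) of module %s extends beyond total_len = %.3f",
                 bad[1], bad[2], module, total_len), call. = FALSE)
  }
  n <- length(seq(0, total_len, by = dt))
  x <- numeric(n)
  for (i in seq_len(nrow(m))) {
    lo <- m[i, 1] / dt # interval edges in cell units
    hi <- m[i, 2] / dt
    k <- max(0L, floor(lo)):min(n - 1L, ceiling(hi))
    x[k + 1L] <- x[k + 1L] + pmax(0, pmin(k + 1, hi) - pmax(k, lo))
  }
  attr(x, "dt") <- dt
  pmin(x, 1)
}

#' Convolve a demand function with the HRF and sample at scan times
#'
#' Computes the discrete convolution at resolution `dt`, scales by `dt`
#' (so that each active period contributes one HRF per unit time, and the
#' responses of separate periods sum), and samples the result at the scan
#' times of `scans` (nearest grid point, no interpolation).
#'
#' @param boxcar Sampled demand function from [demand_to_boxcar()] (any
#'   nonnegative amplitude is allowed; 0--1 for plain demand).
#' @param kernel Sampled kernel from [hrf_kernel()]; must share `dt`.
#' @param scans A [scan_grid()].
#' @return Numeric vector of length `scans$n_scans`; times past the end of
#'   the convolved support are 0.
#' @export
convolve_predict <- function(boxcar, kernel, scans) {
  dt <- attr(boxcar, "dt")
  if (is.null(dt) || is.null(attr(kernel, "dt")) ||
      abs(dt - attr(kernel, "dt")) > 1e-12) {
    stop("boxcar and kernel must be sampled at the same dt", call. = FALSE)
  }
  n <- length(boxcar) + length(kernel) - 1L
  y <- stats::convolve(boxcar, rev(kernel), type = "open") * dt
  idx <- round(scan_times(scans) / dt) + 1L
  out <- numeric(scans$n_scans)
  ok <- idx >= 1L & idx <= n
  out[ok] <- y[idx[ok]]
  out
}

#' Trial-locked condition averages of a per-scan curve
#'
#' For each condition, windows of `window` scans are cut out at the scan
#' nearest each trial onset, the per-trial baseline (the value at the onset
#' scan) is subtracted, and the windows are averaged.
#'
#' @param prediction Per-scan numeric vector (e.g. from [convolve_predict()]).
#' @param events Data frame with columns `onset` (s) and `condition`.
#' @param window Window length in scans.
#' @param scans The [scan_grid()] on which `prediction` lives.
#' @param baseline Baseline rule; currently `"onset"` (value at onset scan)
#'   or `"none"`.
#' @return Matrix `window x conditions` (columns sorted by condition name);
#'   conditions whose trials all fall outside the run are omitted with a
#'   warning.
#' @export
condition_average <- function(prediction, events, window, scans,
                              baseline = c("onset", "none")) {
  baseline <- match.arg(baseline)
  conds <- sort(unique(events$condition))
  out <- matrix(NA_real_, nrow = window, ncol = length(conds),
                dimnames = list(NULL, conds))
  keep <- logical(length(conds))
  for (j in seq_along(conds)) {
    rows <- which(events$condition == conds[j])
    segs <- list()
    for (i in rows) {
      k0 <- round((events$onset[i] - scans$run_onset) / scans$tr) + 1L
      if (k0 < 1L || k0 + window - 1L > length(prediction)) next
      seg <- prediction[k0:(k0 + window - 1L)]
      if (baseline == "onset") seg <- seg - seg[1L]
      segs[[length(segs) + 1L]] <- seg
    }
    if (!length(segs)) next
    out[, j] <- rowMeans(do.call(cbind, segs))
    keep[j] <- TRUE
  }
  if (!all(keep)) {
    warning("condition(s) with no usable trials omitted: ",
            paste(conds[!keep], collapse = ", "), call. = FALSE)
  }
  out[, keep, drop = FALSE]
}

#' Predicted condition curves for every module of a trace
#'
#' Convenience wrapper: boxcar, convolution and condition averaging for each
#' module present in `trace`.
#'
#' @inheritParams condition_average
#' @param trace A run-level [demand_trace()].
#' @param hrf An [hrf_spec()].
#' @return Named list of `window x conditions` matrices, one per module.
#' @export
predict_module_curves <- function(trace, events, window, scans,
                                  hrf = hrf_spec(), baseline = "onset") {
  kern <- hrf_kernel(hrf)
  total_len <- max(trace_end(trace),
                   scans$run_onset + (scans$n_scans - 1L) * scans$tr)
  out <- list()
  for (mod in names(trace$intervals)) {
    bc <- demand_to_boxcar(trace, mod, dt = hrf$dt, total_len = total_len)
    pred <- convolve_predict(bc, kern, scans)
    out[[mod]] <- condition_average(pred, events, window, scans,
                                    baseline = baseline)
  }
  out
}

#' Write / read predicted curves as TSV (`module  condition  scan  value`)
#'
#' @param curves Named list of `window x conditions` matrices (per module).
#' @param path File path.
#' @return `write_curves` returns `path` invisibly; `read_curves` the list.
#' @export
write_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(mod) {
    m <- curves[[mod]]
    data.frame(module = mod,
               condition = rep(colnames(m), each = nrow(m)),
               scan = rep(seq_len(nrow(m)) - 1L, ncol(m)),
               value = as.vector(m))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$module), function(d) {
    conds <- sort(unique(d$condition))
    vapply(conds, function(cc) d$value[d$condition == cc],
           numeric(sum(d$condition == conds[1])))
  })
}
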