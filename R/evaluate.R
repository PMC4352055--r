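#' Mean ROI time course
#'
#' Unweighted spatial mean over the ROI's voxels at each scan.
#'
#' @param bold 4D array `(x, y, z, scan)` on the ROI's grid.
#' @param roi A [roi_mask()].
#' @param grid Optional [volume_grid()] of `bold` for the grid check.
#' @return Numeric vector, one value per scan.
#' @export
extract_roi_timecourse <- function(bold, roi, grid = NULL) {
  d <- dim(bold)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), roi$grid$dims)) {
    stop("data grid does not match ROI grid", call. = FALSE)
  }
  if (!is.null(grid)) check_same_grid(grid, roi$grid, "data and ROI")
  Y <- matrix(bold, nrow = prod(d[1:3]))
  colMeans(Y[roi$voxels, , drop = FALSE])
}

#' Event-locked percent-signal-change curves
#'
#' Cuts a window of scans at each trial onset, converts it to percent signal
#' change relative to the baseline scan (the onset scan), and averages within
#' condition. Trials whose window extends past the end of the run are dropped
#' with a warning.
#'
#' @param timecourse Per-scan numeric vector (e.g. [extract_roi_timecourse()]).
#' @param events Data frame with `onset` (s) and `condition`.
#' @param window Window length in scans.
#' @param scans The [scan_grid()] of the time course.
#' @return Matrix `window x conditions` of percent change.
#' @export
event_locked_average <- function(timecourse, events, window, scans) {
  conds <- sort(unique(events$condition))
  out <- matrix(NA_real_, window, length(conds), dimnames = list(NULL, conds))
  dropped <- 0L
  for (j in seq_along(conds)) {
    segs <- list()
    for (i in which(events$condition == conds[j])) {
      k0 <- round((events$onset[i] - scans$run_onset) / scans$tr) + 1L
      if (k0 < 1L || k0 + window - 1L > length(timecourse)) {
        dropped <- dropped + 1L
        next
      }
      seg <- timecourse[k0:(k0 + window - 1L)]
      b <- seg[1L]
      segs[[length(segs) + 1L]] <- 100 * (seg - b) / b
    }
    if (length(segs)) out[, j] <- rowMeans(do.call(cbind, segs))
  }
  if (dropped) {
    warning(dropped, " trial(s) extended past the run end and were dropped",
            call. = FALSE)
  }
  out[, colSums(is.na(out)) < nrow(out), drop = FALSE]
}

#' Tucker's congruence coefficient
#'
#' `tcc(x, y) = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, the proportionality of
#' two vectors: 1 for identical (or positively proportional) vectors, -1 for
#' exact opposites, bounded by \[-1, 1\] (Cauchy--Schwarz). Unlike a squared
#' correlation it is sensitive to sign and slope and handles flat curves.
#'
#' @param x,y Numeric vectors of equal length >= 2, each with at least one
#'   nonzero element.
#' @return The coefficient, in \[-1, 1\].
#' @examples
#' tcc(1:5, 1:5)      # 1
#' tcc(1:5, -(1:5))   # -1
#' @export
tcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("tcc needs two vectors of equal length >= 2", call. = FALSE)
  }
  nx <- sum(x^2)
  ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    stop("tcc is undefined for a zero vector", call. = FALSE)
  }
  sum(x * y) / sqrt(nx * ny)
}

#' Squared Pearson correlation
#'
#' The R-squared measure of correspondence: insensitive to slope sign and
#' scale (contrast with [tcc()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Squared correlation in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("r_squared needs two vectors of equal length >= 3", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("r_squared is undefined for zero-variance input", call. = FALSE)
  }
  cor(x, y)^2
}

#' Root-mean-square deviation
#'
#' @param x,y Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((x - y)^2))`, in the units of the inputs.
#' @export
rmsd <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L) {
    stop("rmsd needs two vectors of equal length >= 1", call. = FALSE)
  }
  sqrt(mean((x - y)^2))
}

concat_conditions <- function(curves, conds) {
  as.vector(curves[, conds, drop = FALSE])
}

#' Fit report: model predictions vs ROI data for one module
#'
#' Aggregate statistics (TCC, R-squared, RMSD) are computed on the
#' concatenation of all condition curves; the individual TCC is computed per
#' subject on that subject's concatenated curves and summarized by mean, SD,
#' min and max. Because model predictions are in arbitrary units, a scalar
#' gain fitted by least squares maps the model onto the data before RMSD
#' (TCC and R-squared are scale-invariant and use the raw curves).
#'
#' @param model_curves `window x conditions` matrix of model predictions.
#' @param data_curves `window x conditions` matrix of group-average data
#'   (percent signal change).
#' @param subject_curves Optional list of per-subject `window x conditions`
#'   matrices; subjects missing a condition are dropped with a warning.
#' @param module,mapping Labels stored in the report.
#' @return A list of class `fit_report` with fields `module`, `mapping`,
#'   `tcc`, `tcc_individual` (mean, sd, min, max, n), `r_squared`, `rmsd`,
#'   `gain`.
#' @export
fit_report <- function(model_curves, data_curves, subject_curves = NULL,
                       module = NA_character_, mapping = "data_driven") {
  conds <- intersect(colnames(model_curves), colnames(data_curves))
  if (!length(conds)) stop("model and data share no conditions", call. = FALSE)
  m <- concat_conditions(model_curves, conds)
  d <- concat_conditions(data_curves, conds)
  gain <- sum(m * d) / sum(m^2)
  ind <- c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
           n = 0)
  if (!is.null(subject_curves)) {
    vals <- numeric(0)
    dropped <- 0L
    for (sc in subject_curves) {
      if (!all(conds %in% colnames(sc)) ||
          anyNA(sc[, conds])) {
        dropped <- dropped + 1L
        next
      }
      vals <- c(vals, tcc(m, concat_conditions(sc, conds)))
    }
    if (dropped) {
      warning(dropped, " subject(s) missing a condition were dropped",
              call. = FALSE)
    }
    if (length(vals)) {
      ind <- c(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
               min = min(vals), max = max(vals), n = length(vals))
    }
  }
  structure(list(module = module, mapping = mapping,
                 tcc = tcc(m, d),
                 tcc_individual = ind,
                 r_squared = r_squared(m, d),
                 rmsd = rmsd(d, gain * m),
                 gain = gain),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s (%s): TCC %.2f, Ind. TCC %.2f (%.2f; %.2f-%.2f), R2 %.2f, RMSD %.2f\n",
              x$module, x$mapping, x$tcc, x$tcc_individual["mean"],
              x$tcc_individual["sd"], x$tcc_individual["min"],
              x$tcc_individual["max"], x$r_squared, x$rmsd))
  invisible(x)
}

#' Tabulate fit reports
#'
#' @param reports List of [fit_report()] objects.
#' @return Data frame with one row per report, mirroring the standard fit
#'   table columns (TCC, individual TCC mean/sd/range, R-squared, RMSD).
#' @export
fit_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(module = r$module, mapping = r$mapping, tcc = r$tcc,
               ind_tcc_mean = unname(r$tcc_individual["mean"]),
               ind_tcc_sd = unname(r$tcc_individual["sd"]),
               ind_tcc_min = unname(r$tcc_individual["min"]),
               ind_tcc_max = unname(r$tcc_individual["max"]),
               r_squared = r$r_squared, rmsd = r$rmsd)
  }))
}

#' Behavioral filter configuration
#'
#' @param accuracy_cutoff Subjects scoring at or below this proportion
#'   correct are excluded entirely (default 0.85; the retained boundary is
#'   strictly above 85%).
#' @param rt_sd_cutoff Among correct trials, trials with RT above
#'   `mean + rt_sd_cutoff * sd` (per subject x condition) are removed
#'   (default 2; one-sided upper cut, since slow outliers are the concern).
#' @return A list of class `behavioral_filter_config`.
#' @export
behavioral_filter_config <- function(accuracy_cutoff = 0.85,
                                     rt_sd_cutoff = 2) {
  if (accuracy_cutoff <= 0 || accuracy_cutoff >= 1 || rt_sd_cutoff <= 0) {
    stop("need 0 < accuracy_cutoff < 1 and rt_sd_cutoff > 0", call. = FALSE)
  }
  structure(list(accuracy_cutoff = accuracy_cutoff,
                 rt_sd_cutoff = rt_sd_cutoff),
            class = "behavioral_filter_config")
}

#' Filter trials by accuracy and response-time outliers
#'
#' First drops whole subjects whose overall accuracy is at or below the
#' cutoff; then, among the remaining subjects' correct trials, drops trials
#' whose RT exceeds `mean + k*sd` computed per subject x condition. Cells
#' with fewer than two trials have an undefined SD and receive no RT filter
#' (logged).
#'
#' @param trials Data frame with columns `subject`, `condition`, `rt`,
#'   `correct` (logical or 0/1).
#' @param config A [behavioral_filter_config()].
#' @return List with `trials` (retained correct trials), `excluded_subjects`,
#'   and `log` (data.frame of per-step counts, including cells skipped for
#'   undefined SD).
#' @export
filter_behavior <- function(trials, config = behavioral_filter_config()) {
  need <- c("subject", "condition", "rt", "correct")
  if (!all(need %in% names(trials))) {
    stop("trials must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  acc <- tapply(as.logical(trials$correct), trials$subject, mean)
  excluded <- names(acc)[acc <= config$accuracy_cutoff]
  kept <- trials[!trials$subject %in% excluded & as.logical(trials$correct), ,
                 drop = FALSE]
  n_before <- nrow(kept)
  skipped_cells <- 0L
  keep_row <- rep(TRUE, nrow(kept))
  for (cell in split(seq_len(nrow(kept)),
                     list(kept$subject, kept$condition), drop = TRUE)) {
    if (length(cell) < 2L) {
      skipped_cells <- skipped_cells + 1L
      next
    }
    rts <- kept$rt[cell]
    thr <- mean(rts) + config$rt_sd_cutoff * sd(rts)
    keep_row[cell[rts > thr]] <- FALSE
  }
  out <- kept[keep_row, , drop = FALSE]
  log <- data.frame(
    step = c("subjects_excluded", "correct_trials", "rt_outliers_removed",
             "cells_sd_undefined"),
    count = c(length(excluded), n_before, n_before - nrow(out),
              skipped_cells))
  list(trials = out, excluded_subjects = excluded, log = log)
}
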