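#' Module names of the architecture
#'
#' The six processing resources whose activity is tracked: the two perceptual
#' modules (visual, aural), the two hands (manual_left, manual_right),
#' declarative memory, and the problem state (working memory).
#'
#' @return Character vector of the six recognized module labels.
#' @export
module_names <- function() {
  c("visual", "aural", "manual_left", "manual_right",
    "declarative", "problem_state")
}

check_module <- function(module) {
  if (!is.character(module) || !all(module %in% module_names())) {
    bad <- setdiff(as.character(module), module_names())
    stop("unknown module label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(module_names(), collapse = ", "),
         call. = FALSE)
  }
  module
}

#' Demand trace: per-module activity intervals for one run
#'
#' A demand trace records, for each module, the half-open time intervals
#' `[onset, offset)` (seconds from run start) during which that module was
#' busy. Each module proceeds serially, so intervals within a module must be
#' pairwise disjoint and sorted.
#'
#' @param intervals Named list mapping module labels to two-column matrices
#'   (columns `onset`, `offset`, seconds). Empty modules may be omitted.
#' @param run_id Identifier for the run.
#' @return An object of class `demand_trace`.
#' @export
demand_trace <- function(intervals, run_id = "run") {
  check_module(names(intervals))
  intervals <- lapply(intervals, function(m) {
    trial <- attr(m, "trial")
    m <- matrix(as.numeric(m), ncol = 2,
                dimnames = list(NULL, c("onset", "offset")))
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    if (!is.null(trial)) attr(m, "trial") <- trial[ord]
    m
  })
  tr <- structure(list(run_id = run_id, intervals = intervals),
                  class = "demand_trace")
  validate_trace(tr)
  tr
}

validate_trace <- function(trace) {
  for (mod in names(trace$intervals)) {
    m <- trace$intervals[[mod]]
    if (nrow(m) == 0L) next
    if (any(m[, 1] < 0) || any(m[, 2] <= m[, 1])) {
      stop("module ", mod, ": intervals must satisfy 0 <= onset < offset",
           call. = FALSE)
    }
    if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2] - 1e-9)) {
      stop("module ", mod, ": intervals overlap (module seriality violated)",
           call. = FALSE)
    }
  }
  invisible(trace)
}

#' @export
print.demand_trace <- function(x, ...) {
  cat("<demand_trace> run:", x$run_id, "\n")
  for (mod in names(x$intervals)) {
    m <- x$intervals[[mod]]
    cat(sprintf("  %-13s %4d intervals, %.2f s active\n", mod, nrow(m),
                if (nrow(m)) sum(m[, 2] - m[, 1]) else 0))
  }
  invisible(x)
}

#' Total active duration per module
#'
#' @param trace A [demand_trace()].
#' @return Named numeric vector of summed interval lengths (seconds).
#' @export
trace_duration <- function(trace) {
  vapply(trace$intervals, function(m) {
    if (nrow(m)) sum(m[, 2] - m[, 1]) else 0
  }, numeric(1))
}

#' End of the last interval in a trace
#' @param trace A [demand_trace()].
#' @return Time in seconds (0 for an empty trace).
#' @export
trace_end <- function(trace) {
  offs <- unlist(lapply(trace$intervals, function(m) m[, 2]))
  if (length(offs)) max(offs) else 0
}

#' Concatenate trial-level traces into a run trace
#'
#' Shifts each trace by its trial onset and merges per-module interval lists.
#'
#' @param traces List of [demand_trace()] objects (one per trial).
#' @param onsets Numeric vector of trial onsets in seconds, one per trace,
#'   strictly increasing.
#' @param run_id Identifier for the combined run.
#' @return A [demand_trace()] covering the whole run.
#' @export
bind_traces <- function(traces, onsets, run_id = "run") {
  stopifnot(length(traces) == length(onsets))
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("trial onsets must be strictly increasing", call. = FALSE)
  }
  out <- list()
  trial_of <- list()
  for (i in seq_along(traces)) {
    for (mod in names(traces[[i]]$intervals)) {
      m <- traces[[i]]$intervals[[mod]]
      if (!nrow(m)) next
      out[[mod]] <- rbind(out[[mod]], m + onsets[i])
      trial_of[[mod]] <- c(trial_of[[mod]], rep(i, nrow(m)))
    }
  }
  for (mod in names(out)) attr(out[[mod]], "trial") <- trial_of[[mod]]
  demand_trace(out, run_id = run_id)
}

#' Read / write demand traces as tab-separated interval files
#'
#' The on-disk dialect is a TSV with header `module  trial  onset  offset`,
#' times in seconds with at least millisecond precision.
#'
#' @param trace A [demand_trace()]; for traces spanning several trials the
#'   `trial` column is taken from the optional `trial` attribute of each
#'   interval matrix, else 1.
#' @param path File path.
#' @return `read_trace` returns a [demand_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  rows <- do.call(rbind, lapply(names(trace$intervals), function(mod) {
    m <- trace$intervals[[mod]]
    if (!nrow(m)) return(NULL)
    trial <- attr(m, "trial")
    if (is.null(trial)) trial <- rep(1L, nrow(m))
    data.frame(module = mod, trial = trial,
               onset = sprintf("%.4f", m[, 1]),
               offset = sprintf("%.4f", m[, 2]))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("module", "trial", "onset", "offset")
  if (!all(need %in% names(df))) {
    stop("trace file ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  check_module(unique(df$module))
  ints <- lapply(split(df, df$module), function(d) {
    m <- cbind(onset = d$onset, offset = d$offset)[order(d$onset), ,
                                                   drop = FALSE]
    attr(m, "trial") <- d$trial[order(d$onset)]
    m
  })
  demand_trace(ints, run_id = sub("\\.[^.]*$", "", basename(path)))
}
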