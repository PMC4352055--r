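#' Parameters of the multitask demand generator
#'
#' Timing constants for the three component tasks (visual tracking, tone
#' counting, 2-back letter memory) and the threaded scheduler.
#'
#' @param n_tones Tones per counting trial (default 20, over `trial_len` s).
#' @param trial_len Trial length in seconds (default 30).
#' @param response_window Extra seconds to report the tone count (default 10).
#' @param high_tone_range Inclusive range of the number of high tones per
#'   trial (default `c(10, 17)`).
#' @param letter_on Letter presentation time (s, default 1.0).
#' @param letter_blank Blank after each letter (s, default 1.5).
#' @param n_letters Letters per 2-back trial (default 12).
#' @param aural_encode Duration of one aural tone encoding (s).
#' @param visual_encode Duration of one visual encoding (s).
#' @param ps_step Problem-state update duration (s).
#' @param retrieval_dur Declarative retrieval duration for the 2-back
#'   comparison (s).
#' @param motor_step Key-press duration (s).
#' @param swap_store_dur,swap_retrieve_dur Declarative store / retrieve
#'   durations of a problem-state swap (s).
#' @param tracking_sample_dur Duration of one tracking visual sample (s).
#' @return A list of class `multitask_params`.
#' @export
multitask_params <- function(n_tones = 20, trial_len = 30,
                             response_window = 10,
                             high_tone_range = c(10, 17),
                             letter_on = 1.0, letter_blank = 1.5,
                             n_letters = 12,
                             aural_encode = 0.3, visual_encode = 0.3,
                             ps_step = 0.2, retrieval_dur = 0.3,
                             motor_step = 0.2,
                             swap_store_dur = 0.3, swap_retrieve_dur = 0.3,
                             tracking_sample_dur = 0.3) {
  p <- as.list(environment())
  if (p$n_tones <= 0 || p$n_letters <= 0 || p$trial_len <= 0) {
    stop("counts and trial length must be positive", call. = FALSE)
  }
  if (p$high_tone_range[1] < 0 || p$high_tone_range[2] > p$n_tones) {
    stop("high_tone_range must lie within [0, n_tones]", call. = FALSE)
  }
  class(p) <- "multitask_params"
  p
}

#' @keywords internal
multitask_conditions <- function() {
  c("track", "nback", "count", "track+nback", "track+count", "nback+count")
}

# Each task compiles to an ordered list of resource requests:
# data.frame(module, dur, min_start). min_start pins stimulus-locked steps
# (tone/letter onsets); cognition chains greedily after them.
steps_track <- function(p) {
  n <- ceiling(p$trial_len / (p$tracking_sample_dur + p$motor_step))
  data.frame(module = rep(c("visual", "manual_right"), n),
             dur = rep(c(p$tracking_sample_dur, p$motor_step), n),
             min_start = 0)
}

steps_count <- function(p, n_high, response_hand) {
  onsets <- (seq_len(p$n_tones) - 0.5) * p$trial_len / p$n_tones
  high <- sort(sample(p$n_tones, n_high))
  rows <- list()
  for (i in seq_len(p$n_tones)) {
    rows[[length(rows) + 1L]] <-
      data.frame(module = "aural", dur = p$aural_encode, min_start = onsets[i])
    if (i %in% high) {
      rows[[length(rows) + 1L]] <-
        data.frame(module = "problem_state", dur = p$ps_step, min_start = onsets[i])
    }
  }
  # response phase: one key press per increment plus submit
  for (k in seq_len(n_high + 1L)) {
    rows[[length(rows) + 1L]] <-
      data.frame(module = response_hand, dur = p$motor_step,
                 min_start = p$trial_len)
  }
  do.call(rbind, rows)
}

steps_nback <- function(p) {
  pitch <- p$letter_on + p$letter_blank
  onsets <- (seq_len(p$n_letters) - 1L) * pitch
  rows <- list()
  for (i in seq_len(p$n_letters)) {
    rows[[length(rows) + 1L]] <-
      data.frame(module = "visual", dur = p$visual_encode, min_start = onsets[i])
    if (i > 2L) {
      rows[[length(rows) + 1L]] <-
        data.frame(module = "declarative", dur = p$retrieval_dur,
                   min_start = onsets[i])
    }
    rows[[length(rows) + 1L]] <-
      data.frame(module = "problem_state", dur = p$ps_step, min_start = onsets[i])
    if (i > 2L) {
      rows[[length(rows) + 1L]] <-
        data.frame(module = "manual_left", dur = p$motor_step,
                   min_start = onsets[i])
    }
  }
  do.call(rbind, rows)
}

# Greedy threaded scheduler. Modules are serial resources; each thread's
# requests execute in order; a busy module queues the other thread
# first-come-first-served. When two threads could start at the same instant
# the thread whose previous step completed earlier wins; remaining ties break
# by fixed task order (track < nback < count). When `swap` is TRUE, a change
# of problem-state ownership first stores then retrieves via declarative
# memory on the incoming thread's timeline.
run_scheduler <- function(threads, swap = FALSE,
                          swap_store = 0.3, swap_retrieve = 0.3) {
  order_rank <- seq_along(threads)
  idx <- rep(1L, length(threads))
  avail <- rep(0, length(threads))
  module_free <- setNames(rep(0, length(module_names())), module_names())
  ps_owner <- NA_integer_
  ints <- list()
  n_swaps <- 0L
  emit <- function(module, start, dur) {
    ints[[module]] <<- rbind(ints[[module]], c(start, start + dur))
    module_free[module] <<- start + dur
    start + dur
  }
  repeat {
    active <- which(vapply(threads, nrow, 0L) >= idx)
    if (!length(active)) break
    starts <- vapply(active, function(i) {
      st <- threads[[i]][idx[i], ]
      max(avail[i], st$min_start, module_free[[st$module]])
    }, numeric(1))
    pick <- active[order(starts, avail[active], order_rank[active])][1L]
    st <- threads[[pick]][idx[pick], ]
    if (swap && st$module == "problem_state" &&
        !is.na(ps_owner) && ps_owner != pick) {
      # swap the problem state out via declarative memory before using it
      s0 <- max(avail[pick], st$min_start, module_free[["declarative"]])
      s1 <- emit("declarative", s0, swap_store)
      s1 <- max(s1, module_free[["declarative"]])
      avail[pick] <- emit("declarative", s1, swap_retrieve)
      n_swaps <- n_swaps + 1L
    }
    s <- max(avail[pick], st$min_start, module_free[[st$module]])
    avail[pick] <- emit(st$module, s, st$dur)
    if (st$module == "problem_state") ps_owner <- pick
    idx[pick] <- idx[pick] + 1L
  }
  list(intervals = ints, n_swaps = n_swaps)
}

#' Generate the demand trace of one multitask trial
#'
#' Builds each component task's ordered resource requests and runs them
#' through a greedy threaded scheduler in which modules are serial resources
#' (a module busy with one task queues the other, first-come-first-served).
#' Tone counting uses the aural module plus problem-state count updates;
#' 2-back uses visual encoding, declarative retrieval, problem-state updates
#' and left-hand responses; tracking alternates visual samples and right-hand
#' key presses. In the `nback+count` condition both tasks need the problem
#' state, so every ownership handover inserts a declarative store plus
#' retrieve (the swap). Counting responses use the right hand except when
#' combined with tracking (which occupies it), matching the task assignment.
#'
#' @param condition One of `track`, `nback`, `count`, `track+nback`,
#'   `track+count`, `nback+count`.
#' @param params A [multitask_params()].
#' @return A [demand_trace()] with attributes `n_high` (number of high tones,
#'   `NA` for conditions without counting) and `n_swaps`.
#' @export
generate_multitask_trace <- function(condition = "track",
                                     params = multitask_params()) {
  condition <- match.arg(condition, multitask_conditions())
  tasks <- strsplit(condition, "+", fixed = TRUE)[[1]]
  n_high <- NA_integer_
  threads <- list()
  # fixed task order: track < nback < count
  for (task in c("track", "nback", "count")) {
    if (!task %in% tasks) next
    threads[[task]] <- switch(task,
      track = steps_track(params),
      nback = steps_nback(params),
      count = {
        n_high <- sample(seq(params$high_tone_range[1],
                             params$high_tone_range[2]), 1L)
        hand <- if ("track" %in% tasks) "manual_left" else "manual_right"
        steps_count(params, n_high, hand)
      })
  }
  res <- run_scheduler(threads, swap = identical(sort(tasks), c("count", "nback")),
                       swap_store = params$swap_store_dur,
                       swap_retrieve = params$swap_retrieve_dur)
  tr <- demand_trace(res$intervals, run_id = condition)
  attr(tr, "n_high") <- n_high
  attr(tr, "n_swaps") <- res$n_swaps
  tr
}

#' Simulate a full multitask session (one run of one subject)
#'
#' Trials last 30 s (40 s for conditions involving tone counting, which
#' append a 10 s response window) and are separated by a fixation gap. The
#' schedule balances the six single- and dual-task conditions.
#'
#' @param n_trials Number of trials (default 72, i.e. 12 per condition).
#' @param params A [multitask_params()].
#' @param iti Fixation gap between trials in seconds (default 4).
#' @return List with `trace`, `events` and `run_len` as [algebra_session()].
#' @export
multitask_session <- function(n_trials = 72, params = multitask_params(),
                              iti = 4) {
  conds <- multitask_conditions()
  sched <- sample(rep(conds, length.out = n_trials))
  onsets <- numeric(n_trials)
  traces <- vector("list", n_trials)
  dur <- numeric(n_trials)
  t <- 0
  for (i in seq_len(n_trials)) {
    traces[[i]] <- generate_multitask_trace(sched[i], params)
    d <- params$trial_len +
      if (grepl("count", sched[i])) params$response_window else 0
    onsets[i] <- t
    dur[i] <- d
    t <- t + d + iti
  }
  ev <- data.frame(onset = onsets, duration = dur, condition = sched,
                   rt = dur, correct = TRUE)
  list(trace = bind_traces(traces, onsets, run_id = "multitask"),
       events = ev, run_len = t)
}
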