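#' Value of a pyramid problem
#'
#' A pyramid problem `base $ height` denotes repeated addition starting at
#' `base` with each successive term one less than the previous:
#' `4 $ 3 = 4 + 3 + 2 = 9`.
#'
#' @param base Starting value (integer, >= 1).
#' @param height Number of terms (integer, `1 <= height <= base`).
#' @return The pyramid value, an integer.
#' @examples
#' pyramid_value(4, 3) # 9
#' pyramid_value(9, 5) # 35
#' @export
pyramid_value <- function(base, height) {
  if (length(base) != 1L || length(height) != 1L ||
      base < 1 || height < 1 || height > base ||
      base != round(base) || height != round(height)) {
    stop("invalid pyramid problem: need integers base >= 1, 1 <= height <= base",
         call. = FALSE)
  }
  sum(base - seq_len(height) + 1L)
}

#' Solve a pyramid problem with one unknown
#'
#' Mimics the solution procedure of the task model. With the value unknown,
#' the solver performs the iterated addition chain (`height - 1` additions,
#' starting with `base + (base - 1)`). With the height unknown, it runs the
#' same chain until the running total reaches the target value and reports the
#' number of terms. With the base unknown, it follows a guess-and-check
#' procedure: it guesses a base, evaluates the pyramid for that guess, and
#' reports the guess if correct, guess + 1 if the result was too small, or
#' guess - 1 if too big.
#'
#' @param base,height,value Two of the three must be given; the remaining one
#'   (passed as `NA`) is solved for.
#' @param guess Optional initial guess for the unknown-base procedure. The
#'   default inverts the closed form `value = base*height - height*(height-1)/2`
#'   and rounds, mirroring competent estimation.
#' @return A list with elements `base`, `height`, `value` (solved values),
#'   `unknown` (which slot was solved), `chain` (matrix of additions with
#'   columns `a`, `b`, `sum`), and `solved` (`FALSE` when the procedure's
#'   answer does not actually satisfy the problem).
#' @examples
#' pyramid_solve(base = 4, height = 3, value = NA)$value  # 9
#' pyramid_solve(base = NA, height = 4, value = 26)$base  # 8
#' @export
pyramid_solve <- function(base = NA, height = NA, value = NA, guess = NULL) {
  unknown <- c("base", "height", "value")[is.na(c(base, height, value))]
  if (length(unknown) != 1L) {
    stop("exactly one of base, height, value must be NA", call. = FALSE)
  }

  chain_for <- function(b, n_add) {
    # n_add additions: b + (b-1) + ... ; returns matrix a,b,sum
    if (n_add <= 0L) {
      return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("a", "b", "sum"))))
    }
    tot <- b
    out <- matrix(0, nrow = n_add, ncol = 3,
                  dimnames = list(NULL, c("a", "b", "sum")))
    for (i in seq_len(n_add)) {
      term <- b - i
      out[i, ] <- c(tot, term, tot + term)
      tot <- tot + term
    }
    out
  }

  if (unknown == "value") {
    ch <- chain_for(base, height - 1L)
    v <- pyramid_value(base, height)
    return(list(base = base, height = height, value = v, unknown = "value",
                chain = ch, solved = TRUE))
  }

  if (unknown == "height") {
    # add terms until the running total reaches the target
    tot <- base
    h <- 1L
    rows <- NULL
    while (tot < value && h < base) {
      term <- base - h
      rows <- rbind(rows, c(tot, term, tot + term))
      tot <- tot + term
      h <- h + 1L
    }
    ch <- matrix(if (is.null(rows)) numeric(0) else rows, ncol = 3,
                 dimnames = list(NULL, c("a", "b", "sum")))
    return(list(base = base, height = h, value = value, unknown = "height",
                chain = ch, solved = tot == value))
  }

  # unknown base: guess-and-check
  if (is.null(guess)) guess <- round(value / height + (height - 1) / 2)
  guess <- max(guess, height) # a pyramid needs base >= height
  ch <- chain_for(guess, height - 1L)
  got <- if (nrow(ch)) ch[nrow(ch), "sum"] else guess
  b <- if (got == value) guess else if (got < value) guess + 1L else guess - 1L
  solved <- b >= height && pyramid_value(b, height) == value
  list(base = b, height = height, value = value, unknown = "base",
       chain = ch, solved = solved)
}

#' Count column-addition carries in an addition chain
#'
#' An addition carries when the units digits of its operands sum to 10 or
#' more; e.g. the chain of `9 $ 3 = 9 + 8 + 7` (9+8 and 17+7) has two carries.
#'
#' @param chain Matrix with columns `a` and `b` (the operands), as produced by
#'   [pyramid_solve()]. An empty chain yields 0.
#' @return Integer number of carrying additions.
#' @export
count_carries <- function(chain) {
  if (is.null(chain) || nrow(chain) == 0L) return(0L)
  if (any(chain[, c("a", "b")] < 0)) {
    stop("carry counting requires non-negative operands", call. = FALSE)
  }
  sum(chain[, "a"] %% 10 + chain[, "b"] %% 10 >= 10)
}

#' Parameters of the algebra demand generator
#'
#' @param retrieval_mean Mean declarative retrieval latency in seconds
#'   (default 0.483, the behavioral estimate for arithmetic facts).
#' @param retrieval_shape Shape of the gamma retrieval-latency distribution;
#'   `Inf` makes every retrieval exactly `retrieval_mean`.
#' @param encode_step Duration of one visual encoding step (s).
#' @param ps_step Duration of one problem-state update (s).
#' @param motor_step Duration of one mouse move-and-click (s).
#' @param carry_extra Extra problem-state computation time added per carry (s).
#' @return A list of class `algebra_params`.
#' @export
algebra_params <- function(retrieval_mean = 0.483, retrieval_shape = 2,
                           encode_step = 0.3, ps_step = 0.2,
                           motor_step = 0.75, carry_extra = 0.2) {
  p <- list(retrieval_mean = retrieval_mean, retrieval_shape = retrieval_shape,
            encode_step = encode_step, ps_step = ps_step,
            motor_step = motor_step, carry_extra = carry_extra)
  if (any(unlist(p[c(1, 3:6)]) <= 0)) {
    stop("all algebra durations must be > 0", call. = FALSE)
  }
  class(p) <- "algebra_params"
  p
}

draw_retrieval <- function(n, params) {
  if (is.infinite(params$retrieval_shape)) {
    rep(params$retrieval_mean, n)
  } else {
    rgamma(n, shape = params$retrieval_shape,
           rate = params$retrieval_shape / params$retrieval_mean)
  }
}

#' Generate the demand trace of one pyramid trial
#'
#' Plays through the task model for a single pyramid problem: three visual
#' encodings (base, height, value slots), then one declarative retrieval plus
#' one problem-state update per addition (with an extra problem-state step per
#' carry), then one right-hand mouse click per response digit plus the submit
#' click. All steps run serially on one cognitive thread, so per-module
#' interval lists are automatically disjoint.
#'
#' @param base,height,value Problem slots; exactly one `NA` (the unknown).
#' @param params An [algebra_params()] object.
#' @return A [demand_trace()] with attributes `rt` (seconds; offset of the
#'   last manual interval), `solution` (the [pyramid_solve()] result) and
#'   `n_carries`.
#' @export
generate_algebra_trace <- function(base = 4, height = 3, value = NA,
                                   params = algebra_params()) {
  sol <- pyramid_solve(base = base, height = height, value = value)
  carries <- count_carries(sol$chain)
  ints <- list()
  t <- 0
  add <- function(module, dur) {
    ints[[module]] <<- rbind(ints[[module]], c(t, t + dur))
    t <<- t + dur
  }
  for (k in 1:3) add("visual", params$encode_step)
  n_add <- nrow(sol$chain)
  durs <- draw_retrieval(n_add, params)
  carry_steps <- if (n_add) (sol$chain[, "a"] %% 10 + sol$chain[, "b"] %% 10) >= 10 else logical(0)
  for (k in seq_len(n_add)) {
    add("declarative", durs[k])
    add("problem_state", params$ps_step)
    if (carry_steps[k]) add("problem_state", params$carry_extra)
  }
  answer <- sol[[sol$unknown]]
  n_digits <- nchar(as.character(abs(answer)))
  for (k in seq_len(n_digits + 1L)) add("manual_right", params$motor_step)
  tr <- demand_trace(ints, run_id = sprintf("pyr_%s_%s_%s", base, height, value))
  attr(tr, "rt") <- t
  attr(tr, "solution") <- sol
  attr(tr, "n_carries") <- carries
  tr
}

#' Sample a pyramid problem from a design cell
#'
#' The design crosses base size (small: 4--6, large: 7--9) with height size
#' (small: 2--3, large: 4--5), always respecting `height <= base`, and assigns
#' the unknown slot (value, height, or base) uniformly.
#'
#' @param condition One of `"small_small"`, `"small_large"`, `"large_small"`,
#'   `"large_large"` (base size then height size).
#' @return List with `base`, `height`, `value`, `unknown`.
#' @export
sample_pyramid_problem <- function(condition) {
  parts <- strsplit(condition, "_")[[1]]
  bases <- if (parts[1] == "small") 4:6 else 7:9
  heights <- if (parts[2] == "small") 2:3 else 4:5
  repeat {
    b <- sample(bases, 1L)
    h <- sample(heights, 1L)
    if (h <= b) break
  }
  v <- pyramid_value(b, h)
  unknown <- sample(c("value", "height", "base"), 1L)
  list(base = b, height = h, value = v, unknown = unknown)
}

#' Simulate a full algebra session (one run of one subject)
#'
#' Trials follow the scanner protocol: up to 30 s to solve, then 5 s feedback,
#' 12 s repetition detection and 4 s fixation before the next problem. The
#' condition schedule balances the four base-by-height cells.
#'
#' @param n_trials Number of trials (default 72, i.e. 18 per condition).
#' @param params An [algebra_params()].
#' @param post_trial Seconds between response and next trial onset
#'   (default 21 = 5 feedback + 12 repetition detection + 4 fixation).
#' @return List with `trace` (run-level [demand_trace()]), `events`
#'   (data.frame `onset  duration  condition  rt  correct`) and `run_len`
#'   (seconds).
#' @export
algebra_session <- function(n_trials = 72, params = algebra_params(),
                            post_trial = 21) {
  conds <- c("small_small", "small_large", "large_small", "large_large")
  sched <- sample(rep(conds, length.out = n_trials))
  onsets <- numeric(n_trials)
  traces <- vector("list", n_trials)
  ev <- data.frame(onset = numeric(n_trials), duration = numeric(n_trials),
                   condition = sched, rt = numeric(n_trials),
                   correct = logical(n_trials))
  t <- 0
  for (i in seq_len(n_trials)) {
    pr <- sample_pyramid_problem(sched[i])
    args <- list(base = pr$base, height = pr$height, value = pr$value)
    args[[pr$unknown]] <- NA
    tr <- do.call(generate_algebra_trace,
                  c(args, list(params = params)))
    rt <- min(attr(tr, "rt"), 30)
    onsets[i] <- t
    traces[[i]] <- tr
    ev$onset[i] <- t
    ev$duration[i] <- rt
    ev$rt[i] <- rt
    ev$correct[i] <- attr(tr, "solution")$solved
    t <- t + rt + post_trial
  }
  list(trace = bind_traces(traces, onsets, run_id = "algebra"),
       events = ev, run_len = t)
}
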