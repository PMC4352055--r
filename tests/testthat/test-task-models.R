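test_that("pyramid_value reproduces the worked arithmetic and closed forms", {
  expect_equal(pyramid_value(4, 3), 9)
  expect_equal(pyramid_value(4, 2), 7)
  expect_equal(pyramid_value(9, 3), 24)
  expect_equal(pyramid_value(9, 5), 35)
  expect_equal(pyramid_value(5, 1), 5)
  # closed form: two terms give 2b - 1
  for (b in 2:12) expect_equal(pyramid_value(b, 2), 2 * b - 1)
  expect_error(pyramid_value(3, 5), "invalid")
  expect_error(pyramid_value(0, 1), "invalid")
})

test_that("pyramid_solve inverts pyramid_value for all slots", {
  # unknown value: chain has height - 1 additions and ends at the value
  s <- pyramid_solve(base = 4, height = 3, value = NA)
  expect_equal(s$value, 9)
  expect_equal(unname(s$chain[, "sum"]), c(7, 9))
  expect_equal(nrow(s$chain), 2)

  # unknown height: brute-force enumeration oracle
  for (b in 4:9) {
    for (h in 2:min(b, 5)) {
      v <- pyramid_value(b, h)
      h_oracle <- which(vapply(1:b, function(k) pyramid_value(b, k), 0) == v)[1]
      got <- pyramid_solve(base = b, height = NA, value = v)
      expect_true(got$solved)
      expect_equal(got$height, h_oracle)
    }
  }
  expect_equal(pyramid_solve(base = 5, height = NA, value = 9)$height, 2)
  # unsolvable height
  expect_false(pyramid_solve(base = 4, height = NA, value = 11)$solved)

  # unknown base: brute-force oracle over bases
  for (h in 2:5) {
    for (b_true in max(4, h):9) {
      v <- pyramid_value(b_true, h)
      b_oracle <- (4:9)[vapply(4:9, function(b) h <= b && pyramid_value(b, h) == v,
                               FALSE)]
      got <- pyramid_solve(base = NA, height = h, value = v)
      expect_true(got$solved)
      expect_equal(got$base, b_oracle)
    }
  }
  expect_equal(pyramid_solve(base = NA, height = 4, value = 26)$base, 8)
})

test_that("carry counting matches a column-addition oracle", {
  s93 <- pyramid_solve(base = 9, height = 3, value = NA)
  expect_equal(count_carries(s93$chain), 2)
  for (b in 4:9) {
    for (h in 2:min(b, 5)) {
      ch <- pyramid_solve(base = b, height = h, value = NA)$chain
      oracle <- sum(vapply(seq_len(nrow(ch)),
                           function(i) carry_oracle(ch[i, "a"], ch[i, "b"]) > 0,
                           FALSE))
      expect_equal(count_carries(ch), oracle)
    }
  }
  expect_equal(count_carries(NULL), 0L)
})

test_that("algebra traces follow the trial structure", {
  set.seed(42)
  tr <- generate_algebra_trace(4, 3, NA)
  expect_s3_class(tr, "demand_trace")
  # three visual encodes, one retrieval per addition (chain length 2)
  expect_equal(nrow(tr$intervals$visual), 3)
  expect_equal(nrow(tr$intervals$declarative), 2)
  # one-digit answer: one digit click + submit
  expect_equal(nrow(tr$intervals$manual_right), 2)
  # RT equals the end of the last manual interval and the critical-path sum
  expect_equal(attr(tr, "rt"), max(tr$intervals$manual_right[, 2]))
  total <- sum(trace_duration(tr))
  expect_equal(attr(tr, "rt"), total)

  # carries add one extra problem_state interval each
  tr93 <- generate_algebra_trace(9, 3, NA, params = algebra_params())
  expect_equal(nrow(tr93$intervals$problem_state),
               2 + attr(tr93, "n_carries"))
  expect_equal(attr(tr93, "n_carries"), 2)
})

test_that("retrieval durations center on the configured mean", {
  set.seed(7)
  durs <- c()
  for (i in 1:300) {
    pr <- sample_pyramid_problem(sample(c("small_small", "large_large"), 1))
    args <- list(base = pr$base, height = pr$height, value = pr$value)
    args[[pr$unknown]] <- NA
    tr <- do.call(generate_algebra_trace, args)
    d <- tr$intervals$declarative
    if (!is.null(d)) durs <- c(durs, d[, 2] - d[, 1])
  }
  expect_gt(length(durs), 300)
  expect_lt(abs(mean(durs) - 0.483), 0.02)
  # fixed-constant mode
  trc <- generate_algebra_trace(5, 3, NA,
                                params = algebra_params(retrieval_shape = Inf))
  d <- trc$intervals$declarative
  expect_equal(unname(d[, 2] - d[, 1]), rep(0.483, 2))
})

test_that("multitask traces respect task resource profiles", {
  set.seed(1)
  tr <- generate_multitask_trace("track")
  expect_null(tr$intervals$aural)
  expect_null(tr$intervals$declarative)
  expect_true(nrow(tr$intervals$visual) > 0)

  cnt <- generate_multitask_trace("count")
  expect_equal(nrow(cnt$intervals$aural), 20)
  expect_true(all(cnt$intervals$aural[, 1] < 30))
  expect_true(attr(cnt, "n_high") >= 10 && attr(cnt, "n_high") <= 17)
  # counting alone responds with the right hand; with tracking, the left
  expect_null(cnt$intervals$manual_left)
  tc <- generate_multitask_trace("track+count")
  expect_true(nrow(tc$intervals$manual_left) > 0)

  nb <- generate_multitask_trace("nback")
  expect_equal(nrow(nb$intervals$visual), 12)
  # two-back: retrieval and response only from the third letter on
  expect_equal(nrow(nb$intervals$declarative), 10)
  expect_equal(nrow(nb$intervals$manual_left), 10)
})

test_that("problem-state swapping appears only when two tasks share it", {
  set.seed(2)
  both <- generate_multitask_trace("nback+count")
  expect_gt(attr(both, "n_swaps"), 0)
  expect_equal(attr(generate_multitask_trace("track+nback"), "n_swaps"), 0)
  expect_equal(attr(generate_multitask_trace("nback"), "n_swaps"), 0)
  # swaps add declarative store+retrieve pairs beyond the 2-back retrievals
  nb_dec <- nrow(generate_multitask_trace("nback")$intervals$declarative)
  expect_equal(nrow(both$intervals$declarative),
               nb_dec + 2 * attr(both, "n_swaps"))
})

test_that("scheduler seriality: intervals disjoint within every module", {
  set.seed(3)
  for (cond in c("track", "nback", "count", "track+nback", "track+count",
                 "nback+count")) {
    for (rep in 1:5) {
      tr <- generate_multitask_trace(cond)
      for (m in tr$intervals) {
        if (nrow(m) < 2) next
        expect_true(all(m[-1, 1] >= m[-nrow(m), 2] - 1e-9),
                    label = paste("disjoint intervals in", cond))
      }
    }
  }
})

test_that("generation with equal seeds is bitwise reproducible", {
  set.seed(99); a <- generate_multitask_trace("nback+count")
  set.seed(99); b <- generate_multitask_trace("nback+count")
  expect_identical(a, b)
  set.seed(99); s1 <- algebra_session(n_trials = 6)
  set.seed(99); s2 <- algebra_session(n_trials = 6)
  expect_identical(s1, s2)
})

test_that("sessions balance conditions and respect trial pacing", {
  set.seed(5)
  ses <- algebra_session(n_trials = 72)
  expect_equal(nrow(ses$events), 72)
  expect_equal(as.integer(table(ses$events$condition)), rep(18L, 4))
  # post-response period: 21 s between response and next onset
  gaps <- diff(ses$events$onset) - ses$events$rt[-72]
  expect_true(all(abs(gaps - 21) < 1e-9))

  mts <- multitask_session(n_trials = 72)
  expect_equal(as.integer(table(mts$events$condition)), rep(12L, 6))
})

test_that("trace TSV round-trips exactly to written precision", {
  set.seed(11)
  ses <- algebra_session(n_trials = 3)
  path <- tempfile(fileext = ".tsv")
  write_trace(ses$trace, path)
  back <- read_trace(path)
  for (m in names(ses$trace$intervals)) {
    a <- ses$trace$intervals[[m]]
    b <- back$intervals[[m]]
    expect_equal(c(b[, 1], b[, 2]), c(a[, 1], a[, 2]), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
  expect_error(read_trace({
    p <- tempfile(); writeLines("module\tonset\n", p); p
  }), "lacks column")
})
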