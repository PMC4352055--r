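test_that("design matrix has the expected columns and centering", {
  set.seed(20)
  ses <- algebra_session(n_trials = 4)
  scans <- scan_grid(tr = 2, n_scans = ceiling(ses$run_len / 2) + 1)
  X <- build_design_matrix(ses$trace, hrf_spec(), scans, drift_order = 1)
  mods <- attr(X, "modules")
  expect_setequal(mods, c("visual", "declarative", "problem_state",
                          "manual_right"))
  expect_equal(ncol(X), length(mods) + 1 + 1) # modules + drift + intercept
  expect_true(all(abs(colMeans(X[, mods])) < 1e-10))
  expect_equal(unname(X[, "intercept"]), rep(1, scans$n_scans))

  # module regressor is the convolved prediction, standardized
  kern <- hrf_kernel()
  total <- max(trace_end(ses$trace), (scans$n_scans - 1) * 2)
  ref <- convolve_predict(demand_to_boxcar(ses$trace, "visual", 0.1, total),
                          kern, scans)
  expect_equal(unname(X[, "visual"]), (ref - mean(ref)) / sd(ref),
               tolerance = 1e-12)

  # an empty module is excluded with a warning
  tr2 <- ses$trace
  tr2$intervals$aural <- matrix(numeric(0), ncol = 2)
  expect_warning(X2 <- build_design_matrix(tr2, hrf_spec(), scans),
                 "empty demand")
  expect_false("aural" %in% colnames(X2))

  # two identical module traces are reported as collinear
  tr3 <- ses$trace
  tr3$intervals$aural <- tr3$intervals$visual
  expect_error(build_design_matrix(tr3, hrf_spec(), scans),
               "collinear|rank deficient")
})

test_that("first-level OLS recovers exact and permuted signals", {
  set.seed(21)
  ses <- algebra_session(n_trials = 3)
  scans <- scan_grid(tr = 2, n_scans = ceiling(ses$run_len / 2) + 1)
  X <- build_design_matrix(ses$trace, hrf_spec(), scans)
  n <- scans$n_scans
  # noise-free voxel = 2.5 x regressor (plus baseline): beta exact
  Y <- cbind(100 + 2.5 * X[, "visual"],
             rnorm(n),
             rep(1, n)) # zero-variance voxel
  fit <- first_level_fit(Y, X)
  expect_equal(unname(fit$beta[1, "visual"]), 2.5, tolerance = 1e-10)
  expect_equal(fit$df, n - ncol(X))
  expect_false(fit$mask[3]) # constant voxel excluded
  expect_true(all(is.na(fit$beta[3, ])))

  # permuting rows of data and design identically leaves betas unchanged
  perm <- sample(n)
  fit_p <- first_level_fit(Y[perm, 1:2], X[perm, ])
  expect_equal(fit_p$beta[1:2, ], fit[["beta"]][1:2, ], tolerance = 1e-10)

  expect_error(first_level_fit(Y[-1, ], X), "scans")
})

test_that("null t statistics are calibrated (Monte Carlo, 10 seeds)", {
  set.seed(22)
  ses <- algebra_session(n_trials = 3)
  scans <- scan_grid(tr = 2, n_scans = ceiling(ses$run_len / 2) + 1)
  X <- build_design_matrix(ses$trace, hrf_spec(), scans)
  q <- qt(0.999, df = scans$n_scans - ncol(X))
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    set.seed(1000 + s)
    Y <- matrix(rnorm(scans$n_scans * 2000), scans$n_scans, 2000)
    fit <- first_level_fit(Y, X)
    hits <- hits + sum(abs(fit$t[, "visual"]) > q)
    total <- total + 2000L
  }
  rate <- hits / total # expected 0.002 (two-sided at the 0.999 quantile)
  expect_gt(rate, 0.0008)
  expect_lt(rate, 0.0040)
})

test_that("group map matches the textbook one-sample t and edge cases", {
  grid <- toy_grid(4)
  nv <- n_voxels(grid)
  set.seed(23)
  betas <- lapply(1:18, function(s) rnorm(nv, mean = 0.5))
  gm <- group_map(betas, grid)
  # oracle: t.test at a voxel
  v <- 7
  vals <- vapply(betas, `[`, 0, v)
  expect_equal(gm$t[v], unname(t.test(vals)$statistic), tolerance = 1e-10)
  expect_equal(gm$df, 17)
  expect_equal(gm$p[v], unname(t.test(vals)$p.value), tolerance = 1e-10)

  # identical nonzero betas: capped t, floored p
  same <- lapply(1:5, function(s) rep(2, nv))
  gs <- group_map(same, grid)
  expect_equal(gs$t[1], 1e6)
  expect_lt(gs$p[1], 1e-20) # at the t cap for df = 4
  # betas symmetric around zero: t = 0, p = 1
  sym <- lapply(c(-2, -1, 0, 1, 2), function(m) rep(m, nv))
  g0 <- group_map(sym, grid)
  expect_equal(g0$t[1], 0)
  expect_equal(g0$p[1], 1)
  expect_error(group_map(betas[1:2], grid), "at least 3")
  expect_error(group_map(c(betas[1:3], list(rnorm(10))), grid),
               "different grids")
})

test_that("group power at p<0.001 matches the noncentral-t closed form", {
  grid <- volume_grid(c(30, 10, 10), 4, origin = c(0, 0, 0))
  nv <- n_voxels(grid)
  n <- 18
  set.seed(24)
  betas <- lapply(1:n, function(s) rnorm(nv, mean = 1, sd = 1)) # d = 1
  gm <- group_map(betas, grid)
  q <- qt(1 - 0.001 / 2, df = n - 1)
  power_mc <- mean(abs(gm$t) > q)
  ncp <- sqrt(n) * 1
  power_th <- 1 - pt(q, n - 1, ncp) + pt(-q, n - 1, ncp)
  expect_lt(abs(power_mc - power_th), 0.04)
})

test_that("cluster thresholding filters by extent and orders by peak", {
  set.seed(25)
  grid <- toy_grid(16)
  map <- make_toy_statmap(grid, list(
    list(center = c(-16, -16, -16), size = 249, peak_t = 20),
    list(center = c(16, 16, 16), size = 251, peak_t = 30)))
  cl <- threshold_clusters(map, p_thresh = 1e-7, min_extent = 250)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$extent, 251)
  expect_equal(sort(which(cl$labels == 1L)), attr(map, "blob_voxels")[[2]])

  # both survive at a lower extent; labels ordered by peak |t|
  cl2 <- threshold_clusters(map, 1e-7, min_extent = 100)
  expect_equal(nrow(cl2$clusters), 2)
  expect_gt(abs(cl2$clusters$peak_t[1]), abs(cl2$clusters$peak_t[2]))

  # empty result allowed
  null_map <- make_toy_statmap(grid, list())
  expect_equal(nrow(threshold_clusters(null_map)$clusters), 0)

  # idempotence: re-thresholding the surviving support changes nothing
  keep <- which(cl2$labels > 0L)
  map2 <- map
  map2$p[setdiff(seq_len(n_voxels(grid)), keep)] <- 1
  cl3 <- threshold_clusters(map2, 1e-7, min_extent = 100)
  expect_equal(cl3$labels, cl2$labels)
  expect_equal(cl3$clusters$extent, cl2$clusters$extent)
})

test_that("exclusive contrast isolates unique variance and is antisymmetric", {
  set.seed(26)
  grid <- volume_grid(c(5, 5, 2), 4, origin = c(0, 0, 0))
  nv <- n_voxels(grid)
  n <- 60
  xa <- rnorm(n)
  xb <- 0.3 * xa + rnorm(n) # correlated but not collinear
  X <- cbind(A = xa - mean(xa), B = xb - mean(xb), intercept = 1)
  bold <- lapply(1:4, function(s) {
    Y <- matrix(rnorm(n * nv, sd = 0.1), n, nv)
    Y[, 1] <- Y[, 1] + 2 * xa # voxel 1 driven purely by A
    Y + 100
  })
  designs <- rep(list(X), 4)
  mapA <- exclusive_contrast(bold, designs, "A", "B", grid)
  expect_gt(mapA$t[1], 0)
  mapB <- exclusive_contrast(bold, designs, "B", "A", grid)
  expect_equal(mapB$t, -mapA$t, tolerance = 1e-10)

  # collinear pair rejected
  Xc <- cbind(A = xa, B = xa + rnorm(n, sd = 1e-4), intercept = 1)
  expect_error(exclusive_contrast(bold, rep(list(Xc), 4), "A", "B", grid),
               "collinear")
  expect_error(exclusive_contrast(bold, designs, "A", "zz", grid),
               "must both be in the design")
})
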