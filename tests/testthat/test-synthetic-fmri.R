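test_that("ground-truth spheres match analytic volume and stay disjoint", {
  grid <- volume_grid() # default 40 x 48 x 40 at 4 mm
  truth <- make_truth(grid, module_centers(), radius_mm = 12)
  vol_vox <- 4^3
  analytic <- 4 / 3 * pi * 12^3 / vol_vox
  for (mod in names(truth$regions)) {
    n <- length(truth$regions[[mod]]$voxels)
    expect_lt(abs(n - analytic) / analytic, 0.15)
  }
  # pairwise disjointness holds for the default centers at radius 8 too
  expect_silent(make_truth(grid, module_centers(), radius_mm = 8))
  # overlapping spheres are rejected by module pair
  expect_error(
    make_truth(grid, list(visual = c(0, 0, 0), aural = c(6, 0, 0)),
               radius_mm = 10),
    "overlap.*visual.*aural")
  # radius below the voxel size still yields one voxel
  t1 <- make_truth(grid, list(visual = c(-30, -84, 15)), radius_mm = 1)
  expect_gte(length(t1$regions$visual$voxels), 1)
})

test_that("noise-free simulation is the generative identity", {
  set.seed(50)
  grid <- volume_grid(c(10, 10, 10), 4, origin = c(-38 - 16, -50 - 16, 48 - 16))
  truth <- make_truth(grid, list(problem_state = c(-38, -50, 48)),
                      radius_mm = 8)
  ses <- algebra_session(n_trials = 2)
  scans <- scan_grid(2, ceiling(ses$run_len / 2) + 1)
  run <- simulate_subject_run(ses, truth, scans = scans,
                              noise = noise_model(sigma = 0))
  vox <- truth$regions$problem_state$voxels[1]
  series <- matrix(run$bold, n_voxels(grid))[vox, ]
  expect_equal(series, 100 + run$regressors[, "problem_state"],
               tolerance = 1e-12)
  # out-of-region voxel is flat baseline
  out_vox <- setdiff(seq_len(n_voxels(grid)),
                     truth$regions$problem_state$voxels)[1]
  expect_equal(matrix(run$bold, n_voxels(grid))[out_vox, ],
               rep(100, scans$n_scans))
  # injected regressor has unit SD (amplitude = SNR convention)
  expect_equal(sd(run$regressors[, "problem_state"]), 1, tolerance = 1e-12)
})

test_that("AR(1) noise shows the configured lag-1 autocorrelation", {
  rho <- 0.4
  acs <- vapply(1:10, function(s) {
    set.seed(500 + s)
    e <- cogmap:::draw_noise(noise_model(sigma = 1, kind = "ar1", ar_rho = rho),
                             400, 50)
    mean(apply(e, 2, function(x) cor(x[-1], x[-length(x)])))
  }, 0)
  expect_lt(abs(mean(acs) - rho), 0.03)
  # marginal SD stays near sigma
  set.seed(501)
  e <- cogmap:::draw_noise(noise_model(sigma = 2, kind = "ar1", ar_rho = rho),
                           2000, 20)
  expect_lt(abs(sd(as.vector(e)) - 2), 0.1)
})

test_that("out-of-region first-level t values are null-calibrated", {
  set.seed(51)
  grid <- volume_grid(c(8, 8, 8), 4, origin = c(-54, -66, 32))
  truth <- make_truth(grid, list(problem_state = c(-38, -50, 48)),
                      radius_mm = 6)
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    set.seed(600 + s)
    ses <- algebra_session(n_trials = 3)
    scans <- scan_grid(2, ceiling(ses$run_len / 2) + 1)
    run <- simulate_subject_run(ses, truth, scans = scans,
                                noise = noise_model(sigma = 1))
    X <- build_design_matrix(ses$trace, hrf_spec(), scans)
    fit <- first_level_fit(run$bold, X)
    outside <- setdiff(which(fit$mask), truth$regions$problem_state$voxels)
    q <- qt(0.995, fit$df)
    hits <- hits + sum(abs(fit$t[outside, "problem_state"]) > q)
    total <- total + length(outside)
  }
  rate <- hits / total # nominal 0.01
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.02)
})

test_that("group simulation respects schedules and master-seed determinism", {
  grid <- volume_grid(c(8, 8, 8), 4, origin = c(-54, -66, 32))
  truth <- make_truth(grid, list(problem_state = c(-38, -50, 48)),
                      radius_mm = 6)
  g1 <- simulate_group("algebra", n_subjects = 3, n_trials = 4, truth = truth,
                       seed = 7)
  g2 <- simulate_group("algebra", n_subjects = 3, n_trials = 4, truth = truth,
                       seed = 7)
  expect_identical(g1[[2]]$bold, g2[[2]]$bold)
  expect_identical(g1[[3]]$events, g2[[3]]$events)
  expect_equal(nrow(g1[[1]]$events), 4)
  expect_error(simulate_group("algebra", n_subjects = 2, truth = truth),
               "n_subjects >= 3")

  # full-size schedules carry the documented per-condition counts
  set.seed(52)
  alg <- algebra_session(n_trials = 72)
  expect_equal(as.integer(table(alg$events$condition)), rep(18L, 4))
  mt <- multitask_session(n_trials = 72)
  expect_equal(as.integer(table(mt$events$condition)), rep(12L, 6))
})

test_that("toy stat maps have exact blob sizes and auto-seedable peaks", {
  set.seed(53)
  grid <- toy_grid(16)
  map <- make_toy_statmap(grid, list(
    list(center = c(-18, -18, -18), size = 249),
    list(center = c(18, 18, 18), size = 251)))
  supra <- which(map$p < 1e-7)
  comps <- cogmap:::connected_components(supra, grid$dims, 26)
  expect_setequal(vapply(comps, length, 0L), c(249L, 251L))
  # peak sits at the blob center, so seed = "auto" lands there
  blob <- attr(map, "blob_voxels")[[2]]
  peak <- blob[which.max(abs(map$t[blob]))]
  ctr_vox <- world_voxel(grid, matrix(c(18, 18, 18), ncol = 3))
  expect_equal(peak, ctr_vox)
  # empty blob list gives a null map
  expect_equal(nrow(threshold_clusters(make_toy_statmap(grid))$clusters), 0)
  expect_error(
    make_toy_statmap(grid, list(list(center = c(0, 0, 0), size = 100),
                                list(center = c(2, 0, 0), size = 100))),
    "collide")
})

test_that("noise -> 0 recovery approaches the exact truth region", {
  set.seed(54)
  grid <- volume_grid(c(14, 14, 14), 4, origin = c(-38 - 26, -50 - 26, 48 - 26))
  truth <- make_truth(grid, list(problem_state = c(-38, -50, 48)),
                      radius_mm = 10, subject_sd = 0)
  n_true <- length(truth$regions$problem_state$voxels)
  res <- create_mapping("algebra", n_subjects = 4, n_trials = 3, truth = truth,
                        noise = noise_model(sigma = 1e-4), p_thresh = 1e-6,
                        min_extent = 10, target_size = n_true, seed = 9)
  roi <- res$rois$problem_state
  expect_equal(dice_overlap(roi, truth$regions$problem_state), 1)
})
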