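test_that("gamma HRF has zero onset, unit peak at p*q", {
  h <- gamma_hrf(hrf_spec(), dt = 0.5)
  expect_equal(h[1], 0)
  expect_true(all(h >= 0))
  # brute-force maximization on a 1 ms grid: the analytic peak is t = p*q
  spec <- hrf_spec()
  tt <- seq(0, 20, by = 0.001)
  hh <- (tt / (spec$p * spec$q))^spec$p * exp(spec$p - tt / spec$q)
  expect_equal(tt[which.max(hh)], 4.704, tolerance = 1e-3)
  h_at_peak <- (1)^spec$p * exp(spec$p - spec$p * spec$q / spec$q)
  expect_identical(h_at_peak, 1)   # h(p*q) = 1 exactly
  expect_equal(max(hh), 1, tolerance = 1e-6)
  expect_equal(spec$p * spec$q, 4.7042)
})

test_that("design matrix has one column per trial plus nuisance columns", {
  ev <- generate_event_schedule(session_config(seed = 2))
  X <- build_design_matrix(ev, 170L, 2, drift_order = 1)
  expect_equal(ncol(X), 22L)
  expect_equal(attr(X, "trial_cols"), 1:20)
  expect_identical(attr(X, "conditions"), ev$trial_type)
  X3 <- build_design_matrix(ev, 170L, 2, drift_order = 3)
  expect_equal(ncol(X3), 24L)
})

test_that("coincident trials raise a rank-deficiency error naming columns", {
  ev <- data.frame(onset = c(10, 10, 40), duration = c(5, 5, 5),
                   trial_type = c("Arm A", "Arm B", "Leg A"))
  expect_error(build_design_matrix(ev, 40L, 2), "rank deficient.*trial")
})

test_that("events outside the run are rejected", {
  ev <- data.frame(onset = 100, duration = 5, trial_type = "Arm A")
  expect_error(build_design_matrix(ev, 20L, 2), "outside the run")
})

test_that("voxel-wise scaling maps every in-mask series to mean 100", {
  out <- make_bs(5, grid = c(8L, 8L, 8L), sigma = 1)
  d <- dim(out$run$data)
  dat <- matrix(out$run$data, prod(d[1:3]), d[4])
  mu <- rowMeans(dat)[as.logical(out$run$mask)]
  expect_equal(mu, rep(100, length(mu)), tolerance = 1e-10)
  expect_true(all(dat[!as.logical(out$run$mask), ] == 0))
  # idempotence at the fixed point
  run2 <- scale_voxelwise(out$run)
  expect_equal(run2$data, out$run$data, tolerance = 1e-12)
  # constant 250 -> constant 100
  r <- out$run
  r$data[] <- 250
  expect_equal(unique(as.numeric(scale_voxelwise(r)$data[r$mask])), 100)
})

test_that("scaling is invariant to positive rescaling of a voxel series", {
  out <- make_bs(6, grid = c(8L, 8L, 8L), sigma = 1)
  run <- simulate_bold(out$events,
                       generate_pattern_map(out$config, 0, 0,
                                            roi_spec = small_roi(c(8L, 8L, 8L)),
                                            seed = derive_test_seed(6, 2)),
                       noise_spec(sigma = 1), out$config,
                       seed = derive_test_seed(6, 3))
  runc <- run
  runc$data <- run$data * 3.7
  expect_equal(scale_voxelwise(runc)$data, scale_voxelwise(run)$data,
               tolerance = 1e-12)
})

test_that("voxels with non-positive mean are dropped from the mask", {
  out <- make_bs(7, grid = c(6L, 6L, 6L), sigma = 1,
                 roi = list(arm = list(lo = c(2, 2, 2), hi = c(2, 2, 2)),
                            leg = list(lo = c(5, 5, 5), hi = c(5, 5, 5))))
  run <- out$run
  idx <- which(as.logical(run$mask))[1]
  co <- arrayInd(idx, dim(run$mask))
  run$data[co[1], co[2], co[3], ] <- 0
  expect_warning(run2 <- scale_voxelwise(run), "excluded from mask")
  expect_false(run2$mask[co[1], co[2], co[3]])
})

test_that("noiseless betas recover the injected amplitudes exactly", {
  grid <- c(6L, 6L, 6L)
  cfg <- session_config(grid_shape = grid, seed = 21)
  mask <- array(TRUE, dim = grid)
  roi <- list(arm = list(lo = c(2, 2, 2), hi = c(3, 3, 3)),
              leg = list(lo = c(5, 2, 2), hi = c(6, 3, 3)))
  pm <- generate_pattern_map(cfg, 1.3, 0.6, roi_spec = roi, mask = mask,
                             seed = 22)
  ev <- generate_event_schedule(cfg)
  run <- simulate_bold(ev, pm, noise_spec(sigma = 0), cfg)
  X <- build_design_matrix(ev, dim(run$data)[4], cfg$tr_s)
  bs <- fit_beta_series(run, X, mask)
  amps <- vapply(pm$condition, as.numeric, numeric(prod(grid)))
  expected <- unname(t(amps[, ev$trial_type]))
  expect_equal(bs$betas, expected, tolerance = 1e-6)
})

test_that("the shared-QR solver matches a naive per-voxel least squares", {
  out <- make_bs(8, grid = c(6L, 6L, 6L), shared = 1, unique = 0.5, sigma = 1,
                 roi = list(arm = list(lo = c(2, 2, 2), hi = c(3, 3, 3)),
                            leg = list(lo = c(5, 5, 5), hi = c(6, 6, 6))),
                 mask = array(TRUE, c(6, 6, 6)))
  X <- unclass(out$design)
  d <- dim(out$run$data)
  dat <- matrix(out$run$data, prod(d[1:3]), d[4])
  vox <- which(as.logical(out$run$mask))
  vox <- vox[seq(1, length(vox), by = 17)]
  for (j in seq_along(vox)) {
    fit <- lm.fit(X, dat[vox[j], ])
    naive <- fit$coefficients[1:20]
    col <- match(vox[j], which(as.logical(out$run$mask)))
    expect_equal(unname(out$bs$betas[, col]), unname(naive),
                 tolerance = 1e-8)
  }
})

test_that("pure linear drift leaves trial betas unchanged", {
  out <- make_bs(9, grid = c(6L, 6L, 6L), sigma = 0.5,
                 roi = list(arm = list(lo = c(2, 2, 2), hi = c(3, 3, 3)),
                            leg = list(lo = c(5, 5, 5), hi = c(6, 6, 6))))
  run <- out$run
  nv <- dim(run$data)[4]
  drift <- seq(-3, 3, length.out = nv)
  run$data <- run$data + rep(drift, each = prod(dim(run$data)[1:3]))
  bs2 <- fit_beta_series(run, out$design)
  expect_equal(bs2$betas, out$bs$betas, tolerance = 1e-8)
})

test_that("two-class relabeling is the deterministic collapse", {
  expect_identical(relabel_two_class(c("Arm A", "Leg B", "Arm B", "Leg A")),
                   c("upper limb", "lower limb", "upper limb", "lower limb"))
  expect_identical(unique(relabel_two_class(rep(c("Arm A", "Arm B"), 3))),
                   "upper limb")
  lab <- rep(c("Arm A", "Arm B", "Leg A", "Leg B"), each = 5)
  expect_equal(unname(table(relabel_two_class(lab))),
               array(c(10L, 10L)), ignore_attr = TRUE)
  expect_error(relabel_two_class("Torso"), "unknown condition")
})
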