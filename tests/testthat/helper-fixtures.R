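# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# Small-grid region boxes that fit inside brain_mask(grid).
small_roi <- function(grid = c(10L, 10L, 10L)) {
  mid <- round(grid / 2)
  list(arm = list(lo = c(2, mid[2] - 1, mid[3] - 1),
                  hi = c(4, mid[2] + 1, mid[3] + 1)),
       leg = list(lo = c(grid[1] - 3, mid[2] - 1, mid[3] - 1),
                  hi = c(grid[1] - 1, mid[2] + 1, mid[3] + 1)))
}

# Full simulate -> scale -> GLM chain on a configurable grid.
make_bs <- function(seed, grid = c(10L, 10L, 10L), shared = 0, unique = 0,
                    sigma = 1, roi = small_roi(grid), mask = NULL,
                    in_mask_only = FALSE, drift_order = 1) {
  cfg <- session_config(grid_shape = as.integer(grid),
                        seed = derive_test_seed(seed, 1))
  pm <- generate_pattern_map(cfg, shared, unique, roi_spec = roi, mask = mask,
                             seed = derive_test_seed(seed, 2))
  ev <- generate_event_schedule(cfg)
  run <- simulate_bold(ev, pm, noise_spec(sigma = sigma), cfg,
                       seed = derive_test_seed(seed, 3),
                       in_mask_only = in_mask_only)
  run <- scale_voxelwise(run)
  X <- build_design_matrix(ev, dim(run$data)[4], cfg$tr_s,
                           drift_order = drift_order)
  list(bs = fit_beta_series(run, X), events = ev, run = run, design = X,
       patterns = pm, config = cfg)
}

derive_test_seed <- function(seed, k) as.integer(seed * 17 + k)

# Direct beta-level fixture (no GLM) for fast decoder unit tests.
make_beta_fixture <- function(seed, n_per_class = 5, n_voxels = 50,
                              signal_voxels = integer(0), amplitude = 0,
                              sigma = 1) {
  conds <- c("Arm A", "Arm B", "Leg A", "Leg B")
  labels4 <- rep(conds, each = n_per_class)
  n <- length(labels4)
  set.seed(seed)
  betas <- matrix(rnorm(n * n_voxels, sd = sigma), n, n_voxels)
  if (length(signal_voxels)) {
    mu <- matrix(rnorm(4 * length(signal_voxels), sd = amplitude), 4)
    betas[, signal_voxels] <- betas[, signal_voxels] +
      mu[match(labels4, conds), , drop = FALSE]
  }
  coords <- arrayInd(seq_len(n_voxels), c(n_voxels, 1L, 1L)) - 1L
  list(betas = betas, labels4 = labels4,
       labels2 = relabel_two_class(labels4),
       voxel_coords = coords, grid_shape = c(n_voxels, 1L, 1L),
       voxel_size_mm = c(3, 3, 3))
}
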