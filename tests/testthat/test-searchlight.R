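# Brute-force offset oracle over a generous cube.
offsets_oracle <- function(radius_mm, vs) {
  r <- 10L
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  keep <- sqrt((g$i * vs[1])^2 + (g$j * vs[2])^2 + (g$k * vs[3])^2) <=
    radius_mm + 1e-9
  m <- as.matrix(g[keep, ])
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

test_that("sphere offsets match brute-force enumeration", {
  o5 <- sphere_offsets(5, c(3, 3, 3))
  expect_equal(nrow(o5), 19L)
  expect_equal(o5, offsets_oracle(5, c(3, 3, 3)), ignore_attr = TRUE)
  o3 <- sphere_offsets(3, c(3, 3, 3))
  expect_equal(nrow(o3), 7L)
  expect_equal(sphere_offsets(0, c(3, 3, 3)),
               matrix(0L, 1, 3), ignore_attr = TRUE)
  # anisotropic voxels and other radii
  for (radius in c(2, 4.5, 6, 10)) {
    for (vs in list(c(3, 3, 3), c(2, 2, 4), c(1.5, 3, 3))) {
      expect_equal(sphere_offsets(radius, vs), offsets_oracle(radius, vs),
                   ignore_attr = TRUE)
    }
  }
})

test_that("searchlight accuracy peaks inside the informative region", {
  grid <- c(10L, 10L, 10L)
  out <- make_bs(71, grid = grid, shared = 0, unique = 2.5, sigma = 1,
                 roi = small_roi(grid))
  cfg <- searchlight_config(decoder = decoder_config(seed = 7))
  m <- searchlight_map(out$bs, "four_class", cfg)
  expect_s3_class(m, "accuracy_map")
  expect_true(all(m$accuracy[m$mask] >= 0 & m$accuracy[m$mask] <= 1,
                  na.rm = TRUE))
  # the best centres must touch the informative boxes (1-voxel halo)
  top <- which(m$accuracy >= sort(m$accuracy[m$mask], decreasing = TRUE)[5],
               arr.ind = TRUE)
  roi <- small_roi(grid)
  in_halo <- function(pt) {
    any(vapply(roi, function(r)
      all(pt >= r$lo - 1) && all(pt <= r$hi + 1), logical(1)))
  }
  expect_true(all(apply(top, 1, in_halo)))
})

test_that("reordering trials (class ranks preserved) leaves the map unchanged", {
  out <- make_bs(72, grid = c(8L, 8L, 8L), shared = 0, unique = 2, sigma = 1,
                 roi = small_roi(c(8L, 8L, 8L)))
  cfg <- searchlight_config(decoder = decoder_config(seed = 3))
  m1 <- searchlight_map(out$bs, "four_class", cfg)
  # group trials by condition; stable order keeps within-class ranks, on
  # which the seeded fold assignment is defined
  perm <- order(match(out$bs$labels4, unique(out$bs$labels4)))
  bs2 <- out$bs
  bs2$betas <- bs2$betas[perm, ]
  bs2$labels4 <- bs2$labels4[perm]
  bs2$labels2 <- bs2$labels2[perm]
  m2 <- searchlight_map(bs2, "four_class", cfg)
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("group searchlight statistics behave at chance and degenerate", {
  grid <- c(6L, 6L, 6L)
  mk <- array(TRUE, dim = grid)
  mk[1, 1, 1] <- FALSE
  base <- array(NA_real_, grid)
  mkmap <- function(vals) {
    a <- base
    a[mk] <- vals
    structure(list(accuracy = a, mask = mk, chance = 0.25, task = "four_class",
                   voxel_size_mm = c(3, 3, 3), n_skipped = 0L),
              class = "accuracy_map")
  }
  nv <- sum(mk)
  set.seed(80)
  maps <- lapply(1:8, function(s) mkmap(0.25 + rnorm(nv, sd = 0.03)))
  g <- group_searchlight_stat(maps)
  expect_equal(dim(g$t_map), grid)
  expect_true(is.na(g$t_map[1, 1, 1]))
  expect_equal(g$df, 7)
  # all-chance maps: one-sided p values centre near 1/2
  expect_gt(mean(g$p_map[mk], na.rm = TRUE), 0.3)
  expect_lt(mean(g$p_map[mk], na.rm = TRUE), 0.7)
  # a voxel elevated by the same constant in all subjects is degenerate
  maps2 <- lapply(1:8, function(s) {
    m <- mkmap(rep(0.25, nv))
    m$accuracy[2, 2, 2] <- 0.40
    m
  })
  expect_message(g2 <- group_searchlight_stat(maps2), "zero-variance")
  expect_true(is.na(g2$p_map[2, 2, 2]))
  expect_gt(g2$n_degenerate, 0)
  expect_error(group_searchlight_stat(maps[1]), "at least two")
})

test_that("cluster extraction matches hand-drawn configurations", {
  grid <- c(8L, 8L, 8L)
  p <- array(1, grid)
  # L-shaped 5-voxel blob
  blob <- rbind(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2), c(4, 3, 2), c(4, 4, 2))
  p[blob] <- c(1e-4, 1e-4, 1e-6, 1e-4, 1e-4)
  ct <- cluster_threshold(p, 0.001, "face")
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$n_voxels, 5L)
  expect_equal(unlist(ct[1, c("peak_i", "peak_j", "peak_k")]),
               c(4, 2, 2) - 1, ignore_attr = TRUE)
  # corner-touching voxels: separate under face, joined under corner
  p2 <- array(1, grid)
  p2[5, 5, 5] <- 1e-4
  p2[6, 6, 6] <- 1e-4
  expect_equal(nrow(cluster_threshold(p2, 0.001, "face")), 2L)
  expect_equal(nrow(cluster_threshold(p2, 0.001, "face+edge")), 2L)
  expect_equal(nrow(cluster_threshold(p2, 0.001, "face+edge+corner")), 1L)
  # edge-touching voxels join at face+edge level
  p3 <- array(1, grid)
  p3[5, 5, 5] <- 1e-4
  p3[6, 6, 5] <- 1e-4
  expect_equal(nrow(cluster_threshold(p3, 0.001, "face")), 2L)
  expect_equal(nrow(cluster_threshold(p3, 0.001, "face+edge")), 1L)
  # empty suprathreshold set gives an empty table
  expect_equal(nrow(cluster_threshold(array(1, grid), 0.001, "face")), 0L)
  # extent threshold flags survivors
  ct2 <- cluster_threshold(p, 0.001, "face", extent_k = 3)
  expect_true(ct2$survives)
  ct3 <- cluster_threshold(p, 0.001, "face", extent_k = 6)
  expect_false(ct3$survives)
})

test_that("Monte-Carlo extent threshold is calibrated and monotone in FWHM", {
  mask <- brain_mask(c(20L, 20L, 20L))
  mc0 <- monte_carlo_cluster_extent(mask, fwhm_mm = 0, voxel_size_mm = c(3, 3, 3),
                                    voxel_p_threshold = 0.001,
                                    alpha_fwe = 0.05, n_iter = 300, seed = 90)
  # white noise: suprathreshold voxels are near-independent, expected
  # count ~ 2.5 per iteration, so pairs are rare and k stays small
  expect_lte(mc0$k, 3L)
  # alpha = 1 accepts every cluster
  mc1 <- monte_carlo_cluster_extent(mask, 6, c(3, 3, 3), 0.001, 1,
                                    n_iter = 100, seed = 91)
  expect_equal(mc1$k, 1L)
  # k is non-decreasing in smoothness at matched seeds
  ks <- vapply(c(0, 6, 12), function(fw)
    monte_carlo_cluster_extent(mask, fw, c(3, 3, 3), 0.001, 0.05,
                               n_iter = 200, seed = 92)$k, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(monte_carlo_cluster_extent(mask, -1, c(3, 3, 3)), "non-negative")
  expect_error(monte_carlo_cluster_extent(mask, 6, c(3, 3, 3), n_iter = 50),
               "at least 100")
})

test_that("smoothed standardized fields keep unit variance everywhere", {
  set.seed(95)
  gs <- c(12L, 12L, 12L)
  acc <- matrix(0, 200, 2)
  for (r in 1:200) {
    z <- somadecode:::smooth_standardize(array(rnorm(prod(gs)), gs), 8,
                                         c(3, 3, 3))
    acc[r, ] <- c(z[1, 1, 1], z[6, 6, 6])  # corner and centre voxel
  }
  expect_equal(sd(acc[, 1]), 1, tolerance = 0.15)
  expect_equal(sd(acc[, 2]), 1, tolerance = 0.15)
})
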