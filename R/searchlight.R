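#' Searchlight configuration
#'
#' @param radius_mm Sphere radius in millimetres (default 5).
#' @param decoder A [decoder_config()] for the per-sphere classifier. No
#'   percentile feature selection is applied inside spheres (a 5-mm sphere
#'   on 3-mm voxels holds at most 19 voxels).
#' @param voxel_p_threshold Uncorrected voxel-wise p threshold (default
#'   0.001).
#' @param alpha_fwe Family-wise-error level for cluster-extent correction.
#' @param n_mc_iter Monte-Carlo iterations for the extent threshold.
#' @param fwhm_mm Assumed smoothness (Gaussian FWHM, mm) of the group map
#'   used by the Monte-Carlo simulation.
#' @param connectivity Cluster connectivity: `"face"` (6 neighbours),
#'   `"face+edge"` (18) or `"face+edge+corner"` (26).
#' @return Object of class `searchlight_config`.
#' @export
searchlight_config <- function(radius_mm = 5, decoder = decoder_config(),
                               voxel_p_threshold = 0.001, alpha_fwe = 0.05,
                               n_mc_iter = 10000, fwhm_mm = 6,
                               connectivity = c("face", "face+edge",
                                                "face+edge+corner")) {
  connectivity <- match.arg(connectivity)
  stop_if_not_scalar_pos(radius_mm, "radius_mm", strict = FALSE)
  stop_if_not_scalar_pos(fwhm_mm, "fwhm_mm", strict = FALSE)
  stop_if_not_scalar_pos(n_mc_iter, "n_mc_iter")
  if (voxel_p_threshold <= 0 || voxel_p_threshold >= 1 ||
      alpha_fwe <= 0 || alpha_fwe > 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(radius_mm = radius_mm, decoder = decoder,
                 voxel_p_threshold = voxel_p_threshold,
                 alpha_fwe = alpha_fwe, n_mc_iter = as.integer(n_mc_iter),
                 fwhm_mm = fwhm_mm, connectivity = connectivity),
            class = "searchlight_config")
}

#' Integer voxel offsets of a searchlight sphere
#'
#' All integer offsets `(i, j, k)` whose Euclidean distance from the
#' centre, in millimetres, is at most `radius_mm`; the centre is included
#' and offsets are sorted lexicographically. With a 5-mm radius on 3-mm
#' isotropic voxels this yields 19 offsets (centre, 6 face neighbours at
#' 3 mm, 12 edge neighbours at ~4.24 mm; corners at ~5.20 mm fall outside).
#'
#' @param radius_mm Sphere radius in millimetres.
#' @param voxel_size_mm Voxel size per axis in millimetres.
#' @return Integer matrix, offsets x 3.
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm = c(3, 3, 3)) {
  stop_if_not_scalar_pos(radius_mm, "radius_mm", strict = FALSE)
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  r <- floor(radius_mm / voxel_size_mm)
  g <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d2 <- (g$i * voxel_size_mm[1])^2 + (g$j * voxel_size_mm[2])^2 +
    (g$k * voxel_size_mm[3])^2
  g <- g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  m <- as.matrix(g[order(g$i, g$j, g$k), , drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Spherical searchlight accuracy map
#'
#' For every in-mask centre voxel, gathers the in-mask voxels of the
#' surrounding sphere (truncated at mask and grid boundaries), runs the
#' same stratified cross-validated linear-SVC decoding as the whole-brain
#' analysis but without percentile feature selection, and stores the mean
#' cross-validated accuracy at the centre. The fold assignment is drawn
#' once from the decoder seed and reused for every centre, making the map
#' independent of centre visiting order. Centres with fewer than two
#' in-mask sphere voxels are skipped (accuracy NA) and counted.
#'
#' @param bs A beta series (with voxel geometry).
#' @param task `"four_class"` or `"two_class"`.
#' @param cfg A [searchlight_config()].
#' @return Object of class `accuracy_map`: list with `accuracy` (3-D
#'   array, NA outside mask), `mask`, `chance`, `n_skipped`, `task`,
#'   `voxel_size_mm`.
#' @export
searchlight_map <- function(bs, task = c("four_class", "two_class"),
                            cfg = searchlight_config()) {
  task <- match.arg(task)
  gs <- bs$grid_shape
  y <- factor(if (task == "four_class") bs$labels4 else bs$labels2)
  x <- bs$betas
  n <- length(y)
  dec <- cfg$decoder
  folds <- stratified_folds(y, dec$n_folds, dec$seed)
  tr_rows <- lapply(seq_len(dec$n_folds), function(f) which(folds != f))
  te_rows <- lapply(seq_len(dec$n_folds), function(f) which(folds == f))
  y_tr <- lapply(tr_rows, function(r) droplevels(y[r]))

  coords1 <- bs$voxel_coords + 1L            # 1-based centre coordinates
  col_of <- array(NA_integer_, dim = gs)
  col_of[coords1] <- seq_len(nrow(coords1))
  off <- sphere_offsets(cfg$radius_mm, bs$voxel_size_mm)
  acc <- array(NA_real_, dim = gs)
  n_skipped <- 0L
  truth_chr <- as.character(y)
  for (v in seq_len(nrow(coords1))) {
    nb <- off
    nb[, 1] <- nb[, 1] + coords1[v, 1]
    nb[, 2] <- nb[, 2] + coords1[v, 2]
    nb[, 3] <- nb[, 3] + coords1[v, 3]
    ok <- nb[, 1] >= 1L & nb[, 1] <= gs[1] & nb[, 2] >= 1L &
      nb[, 2] <= gs[2] & nb[, 3] >= 1L & nb[, 3] <= gs[3]
    cols <- col_of[nb[ok, , drop = FALSE]]
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2L) { n_skipped <- n_skipped + 1L; next }
    correct <- 0L
    for (f in seq_along(tr_rows)) {
      pr <- svm_fold(x[tr_rows[[f]], cols, drop = FALSE], y_tr[[f]],
                     x[te_rows[[f]], cols, drop = FALSE], dec$cost)
      correct <- correct + sum(as.character(pr) == truth_chr[te_rows[[f]]])
    }
    acc[coords1[v, 1], coords1[v, 2], coords1[v, 3]] <- correct / n
  }
  if (n_skipped > 0)
    message(sprintf("searchlight: %d centre(s) skipped (sphere < 2 voxels)",
                    n_skipped))
  mask <- array(FALSE, dim = gs)
  mask[coords1] <- TRUE
  structure(list(accuracy = acc, mask = mask, chance = 1 / nlevels(y),
                 n_skipped = n_skipped, task = task,
                 voxel_size_mm = bs$voxel_size_mm),
            class = "accuracy_map")
}

#' Group-level searchlight statistic map
#'
#' Per-voxel one-sample, one-sided t statistic of (accuracy - chance)
#' across subjects, with its uncorrected p value. Voxels with zero
#' between-subject variance are flagged degenerate (p = NA) rather than
#' passed through as significant.
#'
#' @param maps List of aligned per-subject `accuracy_map`s.
#' @param chance Chance level (default: taken from the first map).
#' @return Object of class `searchlight_group`: list with `t_map`,
#'   `p_map` (3-D arrays), `mask`, `df`, `n_subjects`, `chance`,
#'   `n_degenerate`.
#' @export
group_searchlight_stat <- function(maps, chance = maps[[1]]$chance) {
  if (length(maps) < 2)
    stop("group statistic needs at least two subjects", call. = FALSE)
  gs <- dim(maps[[1]]$accuracy)
  mask <- maps[[1]]$mask
  for (m in maps)
    if (!identical(dim(m$accuracy), gs))
      stop("subject maps have mismatched geometry", call. = FALSE)
  idx <- which(mask)
  a <- vapply(maps, function(m) m$accuracy[idx], numeric(length(idx)))
  ok <- rowSums(is.na(a)) == 0
  n <- length(maps)
  mu <- rowMeans(a)
  s <- sqrt(pmax(0, (rowSums(a^2) - n * mu^2) / (n - 1)))
  tv <- rep(NA_real_, length(idx))
  pv <- rep(NA_real_, length(idx))
  good <- ok & s > 0
  tv[good] <- (mu[good] - chance) / (s[good] / sqrt(n))
  pv[good] <- stats::pt(tv[good], df = n - 1, lower.tail = FALSE)
  n_degenerate <- sum(ok & s == 0)
  if (n_degenerate > 0)
    message(sprintf("group searchlight: %d zero-variance voxel(s) flagged",
                    n_degenerate))
  t_map <- array(NA_real_, gs); t_map[idx] <- tv
  p_map <- array(NA_real_, gs); p_map[idx] <- pv
  structure(list(t_map = t_map, p_map = p_map, mask = mask, df = n - 1,
                 n_subjects = n, chance = chance,
                 n_degenerate = n_degenerate),
            class = "searchlight_group")
}

# Neighbour offsets for the three connectivity schemes.
conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(g))
  keep <- switch(connectivity,
                 "face" = d == 1,
                 "face+edge" = d >= 1 & rowSums(g != 0) <= 2,
                 "face+edge+corner" = d >= 1,
                 stop("unknown connectivity", call. = FALSE))
  g[keep, , drop = FALSE]
}

# Label connected components of a logical 3-D array; returns an integer
# array (0 = background) and the component sizes.
label_clusters <- function(supra, connectivity = "face") {
  gs <- dim(supra)
  off <- conn_offsets(connectivity)
  labels <- array(0L, gs)
  idx <- which(supra)
  if (!length(idx)) return(list(labels = labels, sizes = integer(0)))
  coords <- arrayInd(idx, gs)
  in_set <- array(FALSE, gs); in_set[idx] <- TRUE
  visited <- array(FALSE, gs)
  cur <- 0L
  sizes <- integer(0)
  for (s in seq_along(idx)) {
    if (visited[idx[s]]) next
    cur <- cur + 1L
    stack <- matrix(coords[s, ], 1, 3)
    visited[idx[s]] <- TRUE
    size <- 0L
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      labels[p[1], p[2], p[3]] <- cur
      size <- size + 1L
      nb <- off
      nb[, 1] <- nb[, 1] + p[1]; nb[, 2] <- nb[, 2] + p[2]
      nb[, 3] <- nb[, 3] + p[3]
      ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 &
        nb[, 2] <= gs[2] & nb[, 3] >= 1 & nb[, 3] <= gs[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb)) {
        lin <- nb[, 1] + gs[1] * (nb[, 2] - 1L) + gs[1] * gs[2] * (nb[, 3] - 1L)
        new <- in_set[lin] & !visited[lin]
        if (any(new)) {
          visited[lin[new]] <- TRUE
          stack <- rbind(stack, nb[new, , drop = FALSE])
        }
      }
    }
    sizes[cur] <- size
  }
  list(labels = labels, sizes = sizes)
}

#' Threshold a p map and extract suprathreshold clusters
#'
#' Binarizes the uncorrected p map at `p < voxel_p_threshold`, labels
#' connected components under the configured connectivity, and tabulates
#' them. If `extent_k` is given, clusters with at least that many voxels
#' are marked as surviving the extent threshold.
#'
#' @param p_map 3-D array of uncorrected p values (NA outside mask).
#' @param voxel_p_threshold Voxel-wise threshold.
#' @param connectivity See [searchlight_config()].
#' @param stat_map Optional statistic map used to locate cluster peaks
#'   (defaults to `-log(p)`).
#' @param mask Optional logical mask restricting the clustering.
#' @param extent_k Optional cluster-extent threshold (voxels).
#' @return A `cluster_table` data frame: `cluster`, `n_voxels`,
#'   `peak_i`, `peak_j`, `peak_k` (0-based), `peak_stat`, `survives`;
#'   attribute `labels` holds the label array. Empty table if nothing is
#'   suprathreshold.
#' @export
cluster_threshold <- function(p_map, voxel_p_threshold = 0.001,
                              connectivity = "face", stat_map = NULL,
                              mask = NULL, extent_k = NULL) {
  supra <- !is.na(p_map) & p_map < voxel_p_threshold
  if (!is.null(mask)) supra <- supra & mask
  if (is.null(stat_map)) stat_map <- -log(p_map)
  lab <- label_clusters(supra, connectivity)
  ncl <- length(lab$sizes)
  tab <- data.frame(cluster = integer(0), n_voxels = integer(0),
                    peak_i = integer(0), peak_j = integer(0),
                    peak_k = integer(0), peak_stat = numeric(0),
                    survives = logical(0))
  if (ncl > 0) {
    rows <- lapply(seq_len(ncl), function(cid) {
      idx <- which(lab$labels == cid)
      pk <- idx[which.max(stat_map[idx])]
      co <- arrayInd(pk, dim(p_map)) - 1L
      data.frame(cluster = cid, n_voxels = lab$sizes[cid],
                 peak_i = co[1], peak_j = co[2], peak_k = co[3],
                 peak_stat = stat_map[pk],
                 survives = if (is.null(extent_k)) NA else
                   lab$sizes[cid] >= extent_k)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$n_voxels), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(tab, labels = lab$labels, extent_k = extent_k,
            class = c("cluster_table", "data.frame"))
}

# Separable Gaussian smoothing of a 3-D array, followed by exact
# per-voxel standardization to unit variance for white-noise input
# (sum of squared kernel weights factorizes over axes).
smooth_standardize <- function(arr, fwhm_mm, voxel_size_mm) {
  gs <- dim(arr)
  if (fwhm_mm == 0) return(arr)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / rep_len(voxel_size_mm, 3L)
  ker <- lapply(1:3, function(a) {
    n <- gs[a]
    k <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - j)^2 / (2 * sig[a]^2)))
    k[abs(row(k) - col(k)) > ceiling(4 * sig[a])] <- 0
    k
  })
  x <- matrix(arr, gs[1], gs[2] * gs[3])
  x <- ker[[1]] %*% x
  x <- array(x, gs)
  x <- aperm(x, c(2, 1, 3))
  x <- matrix(x, gs[2], gs[1] * gs[3])
  x <- ker[[2]] %*% x
  x <- aperm(array(x, gs[c(2, 1, 3)]), c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- matrix(x, gs[3], gs[1] * gs[2])
  x <- ker[[3]] %*% x
  x <- aperm(array(x, gs[c(3, 1, 2)]), c(2, 3, 1))
  w <- lapply(ker, function(k) rowSums(k^2))
  sdmap <- sqrt(outer(outer(w[[1]], w[[2]]), w[[3]]))
  x / sdmap
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates `n_iter` Gaussian white-noise volumes on the mask, smooths
#' each to the stated FWHM, standardizes to unit variance, thresholds at
#' the one-sided z equivalent of `voxel_p_threshold`, and records the
#' maximum suprathreshold cluster size. The extent threshold `k` is the
#' smallest integer such that the fraction of iterations whose maximum
#' cluster size reaches `k` is at most `alpha_fwe`; observed clusters of
#' at least `k` voxels are declared FWE-significant.
#'
#' @param mask Logical 3-D array.
#' @param fwhm_mm Assumed smoothness (Gaussian FWHM, mm).
#' @param voxel_size_mm Voxel size per axis (mm).
#' @param voxel_p_threshold One-sided voxel-wise p threshold.
#' @param alpha_fwe Family-wise error level.
#' @param n_iter Number of Monte-Carlo iterations (>= 100).
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity.
#' @return List with `k`, `max_sizes` (per-iteration maxima), `alpha_fwe`,
#'   `n_iter`, `fwhm_mm`.
#' @export
monte_carlo_cluster_extent <- function(mask, fwhm_mm, voxel_size_mm = c(3, 3, 3),
                                       voxel_p_threshold = 0.001,
                                       alpha_fwe = 0.05, n_iter = 10000,
                                       seed = NULL, connectivity = "face") {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be non-negative", call. = FALSE)
  if (n_iter < 100) stop("'n_iter' must be at least 100", call. = FALSE)
  gs <- dim(mask)
  zthr <- stats::qnorm(1 - voxel_p_threshold)
  max_sizes <- integer(n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      z <- smooth_standardize(array(stats::rnorm(prod(gs)), gs),
                              fwhm_mm, voxel_size_mm)
      supra <- mask & z > zthr
      sizes <- label_clusters(supra, connectivity)$sizes
      max_sizes[i] <- if (length(sizes)) max(sizes) else 0L
    }
  })
  frac_ge <- function(k) mean(max_sizes >= k)
  k <- 1L
  while (frac_ge(k) > alpha_fwe) k <- k + 1L
  list(k = k, max_sizes = max_sizes, alpha_fwe = alpha_fwe,
       n_iter = as.integer(n_iter), fwhm_mm = fwhm_mm)
}
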