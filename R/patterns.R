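#' Ellipsoidal brain mask on the simulation grid
#'
#' @param grid_shape Voxel counts per axis.
#' @param radii Ellipsoid semi-axes in voxels (default: inscribed with a
#'   1.5-voxel margin).
#' @param center Ellipsoid centre in voxel units (1-based, default grid centre).
#' @return Logical 3-D array, `TRUE` inside the mask.
#' @export
brain_mask <- function(grid_shape, radii = grid_shape / 2 - 1.5,
                       center = (grid_shape + 1) / 2) {
  stopifnot(length(grid_shape) == 3L, length(radii) == 3L ||
              length(radii) == 1L, length(center) == 3L)
  radii <- rep_len(radii, 3L)
  if (any(radii <= 0)) stop("mask radii must be positive", call. = FALSE)
  d2 <- outer(outer(((seq_len(grid_shape[1]) - center[1]) / radii[1])^2,
                    ((seq_len(grid_shape[2]) - center[2]) / radii[2])^2, "+"),
              ((seq_len(grid_shape[3]) - center[3]) / radii[3])^2, "+")
  d2 <= 1
}

#' Default body-part region boxes for the pattern generator
#'
#' Two disjoint 3x3x3 boxes inside the default mask, loosely mimicking the
#' somatotopic layout in which the upper limb maps laterally and the lower
#' limb medially-superiorly in primary somatosensory cortex: the "arm"
#' region sits laterally (low x) and the "leg" region medially and one
#' slice higher. Boxes are given as 1-based inclusive `lo`/`hi` voxel
#' corners.
#'
#' @param grid_shape Voxel counts per axis.
#' @return Named list with elements `arm` and `leg`, each `list(lo, hi)`.
#' @export
default_roi_spec <- function(grid_shape = c(20L, 20L, 20L)) {
  mid <- round(grid_shape / 2)
  list(
    arm = list(lo = c(mid[1] - 6L, mid[2] - 1L, mid[3] - 1L),
               hi = c(mid[1] - 4L, mid[2] + 1L, mid[3] + 1L)),
    leg = list(lo = c(mid[1] + 3L, mid[2] - 1L, mid[3]),
               hi = c(mid[1] + 5L, mid[2] + 1L, mid[3] + 2L))
  )
}

region_indices <- function(box, grid_shape) {
  if (any(box$lo < 1) || any(box$hi > grid_shape) || any(box$lo > box$hi))
    stop("region box falls outside the grid", call. = FALSE)
  as.matrix(expand.grid(i = box$lo[1]:box$hi[1],
                        j = box$lo[2]:box$hi[2],
                        k = box$lo[3]:box$hi[3]))
}

#' Generate ground-truth spatial activation patterns
#'
#' Builds per-condition 3-D amplitude volumes (in units of the baseline
#' signal, i.e. percent when the baseline is 100) with a coarse body-part
#' structure plus fine condition-unique patterns: each condition volume is
#' the shared component of its body part (constant `shared_amplitude`
#' inside the region) plus a seeded random-sign pattern of magnitude
#' `unique_amplitude` unique to the condition. Binary (arm vs leg)
#' decoding is therefore driven by the coarse regions and four-way
#' decoding by the fine patterns. Amplitudes are zero outside the mask.
#'
#' @param config A [session_config()]; supplies grid shape and condition
#'   names (conditions containing "Arm" map to the arm region, "Leg" to
#'   the leg region).
#' @param shared_amplitude Amplitude of the body-part component.
#' @param unique_amplitude Magnitude of the condition-unique component.
#' @param roi_spec Region boxes as from [default_roi_spec()].
#' @param mask Optional logical brain mask (default [brain_mask()] on the
#'   config grid).
#' @param seed Integer seed for the unique sign patterns.
#' @return An object of class `pattern_map`: list with `condition`
#'   (named list of 3-D arrays), `shared` (arm/leg component arrays),
#'   `mask`, `regions`, `grid_shape`, `voxel_size_mm`.
#' @export
generate_pattern_map <- function(config,
                                 shared_amplitude = 1,
                                 unique_amplitude = 0.5,
                                 roi_spec = default_roi_spec(config$grid_shape),
                                 mask = NULL,
                                 seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  stop_if_not_scalar_pos(shared_amplitude, "shared_amplitude", strict = FALSE)
  stop_if_not_scalar_pos(unique_amplitude, "unique_amplitude", strict = FALSE)
  gs <- config$grid_shape
  if (is.null(mask)) mask <- brain_mask(gs)
  stopifnot(identical(dim(mask), as.integer(gs)))
  idx <- lapply(roi_spec, region_indices, grid_shape = gs)
  lin <- lapply(idx, function(m)
    m[, 1] + gs[1] * (m[, 2] - 1L) + gs[1] * gs[2] * (m[, 3] - 1L))
  if (length(intersect(lin$arm, lin$leg)) > 0)
    stop("body-part regions overlap", call. = FALSE)

  part_of <- function(cn) {
    if (grepl("Arm", cn, fixed = TRUE)) "arm"
    else if (grepl("Leg", cn, fixed = TRUE)) "leg"
    else stop(sprintf("condition '%s' matches no body-part region", cn),
              call. = FALSE)
  }
  zero <- array(0, dim = gs)
  shared <- list(arm = zero, leg = zero)
  for (p in c("arm", "leg")) {
    v <- zero
    keep <- mask[idx[[p]]]
    v[idx[[p]][keep, , drop = FALSE]] <- shared_amplitude
    shared[[p]] <- v
  }
  cond <- with_seed(seed, {
    out <- vector("list", config$n_conditions)
    names(out) <- config$condition_names
    for (cn in config$condition_names) {
      p <- part_of(cn)
      u <- zero
      keep <- mask[idx[[p]]]
      signs <- sample(c(-1, 1), sum(keep), replace = TRUE)
      u[idx[[p]][keep, , drop = FALSE]] <- signs * unique_amplitude
      out[[cn]] <- shared[[p]] + u
    }
    out
  })
  structure(list(condition = cond, shared = shared, mask = mask,
                 regions = roi_spec, grid_shape = gs,
                 voxel_size_mm = config$voxel_size_mm),
            class = "pattern_map")
}

#' @export
print.pattern_map <- function(x, ...) {
  cat(sprintf("Pattern map: %d conditions on %s grid, %d mask voxels\n",
              length(x$condition), paste(x$grid_shape, collapse = "x"),
              sum(x$mask)))
  invisible(x)
}
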