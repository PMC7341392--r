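#' Noise specification for the BOLD simulator
#'
#' Stationary Gaussian noise with optional lag-1 autocorrelation (AR(1)),
#' added on top of a constant baseline.
#'
#' @param sigma Marginal noise standard deviation (signal units).
#' @param ar1 Lag-1 autocorrelation coefficient, `|ar1| < 1`.
#' @param baseline Mean signal level (default 100, so pattern amplitudes
#'   read as percent signal change).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 1, ar1 = 0, baseline = 100) {
  stop_if_not_scalar_pos(sigma, "sigma", strict = FALSE)
  if (!is.numeric(ar1) || length(ar1) != 1L || abs(ar1) >= 1)
    stop("'ar1' must satisfy |ar1| < 1", call. = FALSE)
  structure(list(sigma = sigma, ar1 = ar1, baseline = baseline),
            class = "noise_spec")
}

#' Simulate a noisy event-related BOLD run
#'
#' Forward model: every voxel's series is
#' `baseline + sum over trials of amplitude(condition, voxel) * r_trial(t) + noise`,
#' where `r_trial` is the trial's boxcar convolved with the gamma HRF
#' sampled at the TR (identical to the regressors used by
#' [build_design_matrix()]), and the noise is white Gaussian filtered to
#' lag-1 autocorrelation `ar1` with marginal SD `sigma`. Noise is drawn for
#' every grid voxel (inside and outside the mask), so out-of-mask voxels
#' provide a signal-free background.
#'
#' @param events An `event_table`.
#' @param patterns A [generate_pattern_map()] result.
#' @param noise A [noise_spec()].
#' @param config The [session_config()].
#' @param hrf An [hrf_spec()].
#' @param n_volumes Optional fixed volume count; by default the run is
#'   extended to the last event offset plus 20 s of HRF decay.
#' @param seed Integer seed for the noise draw.
#' @param in_mask_only If TRUE, draw noise only for in-mask voxels and
#'   leave the rest of the grid at the constant baseline -- a cheap mode
#'   for analyses that never leave the mask.
#' @return Object of class `bold_run`: list with `data` (4-D array
#'   x,y,z,t), `tr_s`, `voxel_size_mm`, `mask`.
#' @export
simulate_bold <- function(events, patterns, noise = noise_spec(),
                          config, hrf = hrf_spec(), n_volumes = NULL,
                          seed = NULL, in_mask_only = FALSE) {
  stopifnot(inherits(patterns, "pattern_map"), inherits(noise, "noise_spec"),
            inherits(config, "session_config"))
  gs <- patterns$grid_shape
  amps <- vapply(patterns$condition, function(a) as.numeric(a),
                 numeric(prod(gs)))           # voxels x conditions
  if (any(!is.finite(amps)))
    stop("pattern amplitudes must be finite", call. = FALSE)
  if (is.null(n_volumes))
    n_volumes <- ceiling((max(events$onset + events$duration) + 20) / config$tr_s)
  n_volumes <- as.integer(n_volumes)

  xt <- trial_regressors(events, n_volumes, config$tr_s, hrf)  # vol x trials
  cond <- as.character(events$trial_type)
  if (!all(cond %in% colnames(amps) | cond %in% names(patterns$condition)))
    stop("event conditions missing from the pattern map", call. = FALSE)
  nvox <- prod(gs)
  vox_idx <- if (in_mask_only) which(as.logical(patterns$mask)) else seq_len(nvox)
  # amplitude of each (trial, voxel) = condition amplitude at that voxel
  b <- t(amps[vox_idx, cond, drop = FALSE])   # trials x voxels
  signal <- xt %*% b                          # vol x voxels
  eps <- with_seed(seed, matrix(stats::rnorm(n_volumes * length(vox_idx)),
                                n_volumes, length(vox_idx)))
  if (noise$sigma == 0) {
    eps[] <- 0
  } else if (noise$ar1 != 0) {
    # AR(1) with stationary marginal SD sigma
    eps <- eps * sqrt(1 - noise$ar1^2)
    eps[1, ] <- eps[1, ] / sqrt(1 - noise$ar1^2)
    eps <- stats::filter(eps, noise$ar1, method = "recursive")
    eps <- matrix(as.numeric(eps), n_volumes, length(vox_idx))
    eps <- eps * noise$sigma
  } else {
    eps <- eps * noise$sigma
  }
  dat <- noise$baseline + signal + eps
  arr <- if (in_mask_only) {
    a <- array(noise$baseline, dim = c(gs, n_volumes))
    off <- (seq_len(n_volumes) - 1L) * nvox
    a[rep(vox_idx, n_volumes) + rep(off, each = length(vox_idx))] <- t(dat)
    a
  } else array(t(dat), dim = c(gs, n_volumes))
  structure(list(data = arr, tr_s = config$tr_s,
                 voxel_size_mm = patterns$voxel_size_mm, mask = patterns$mask),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %s voxels x %d volumes (TR %.3g s), %d mask voxels\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}
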