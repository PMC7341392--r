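#' Voxel-wise mean scaling of a BOLD run
#'
#' Divides each in-mask voxel series by its own temporal mean and
#' multiplies by 100, so every scaled in-mask series has mean exactly 100
#' and trial estimates read as percent signal change. Out-of-mask voxels
#' are zeroed. In-mask voxels whose temporal mean is at or below `tol`
#' cannot be scaled and are excluded from the mask with a warning.
#'
#' @param run A `bold_run`.
#' @param mask Logical mask (default `run$mask`).
#' @param tol Positive-mean tolerance.
#' @return A `bold_run` with scaled data and possibly reduced mask.
#' @export
scale_voxelwise <- function(run, mask = run$mask, tol = 1e-6) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  nvox <- prod(d[1:3])
  dat <- matrix(run$data, nvox, d[4])          # voxels x volumes
  mvec <- as.logical(mask)
  mu <- rowMeans(dat)
  bad <- mvec & mu <= tol
  if (any(bad)) {
    warning(sprintf("%d in-mask voxel(s) with temporal mean <= %g excluded from mask",
                    sum(bad), tol), call. = FALSE)
    mvec[bad] <- FALSE
  }
  out <- matrix(0, nvox, d[4])
  out[mvec, ] <- 100 * dat[mvec, , drop = FALSE] / mu[mvec]
  run$data <- array(out, dim = d)
  run$mask <- array(mvec, dim = d[1:3])
  run
}

#' Fit a single-trial beta series by ordinary least squares
#'
#' Solves the LS-A beta-series model: one joint ordinary-least-squares fit
#' per voxel against the full trial-wise design (all trial regressors plus
#' nuisance columns), sharing a single QR factorization of the design
#' across voxels. Trial coefficients are returned; nuisance coefficients
#' (intercept, drift) are discarded.
#'
#' @param run A `bold_run` (typically after [scale_voxelwise()]).
#' @param design A [build_design_matrix()] result with matching volume count.
#' @param mask Logical mask selecting the voxels to fit (default `run$mask`).
#' @return Object of class `beta_series`: list with `betas` (trials x
#'   voxels), `labels4` (condition per trial), `labels2` (body part per
#'   trial), `voxel_coords` (0-based grid indices, voxels x 3),
#'   `grid_shape`, `voxel_size_mm`.
#' @export
fit_beta_series <- function(run, design, mask = run$mask) {
  stopifnot(inherits(run, "bold_run"), inherits(design, "design_matrix"))
  d <- dim(run$data)
  if (d[4] != nrow(design))
    stop(sprintf("run has %d volumes but design has %d rows", d[4],
                 nrow(design)), call. = FALSE)
  mvec <- as.logical(mask)
  dat <- matrix(run$data, prod(d[1:3]), d[4])
  y <- t(dat[mvec, , drop = FALSE])            # volumes x voxels
  qx <- qr(unclass(design))
  if (qx$rank < ncol(design))
    stop("design matrix is rank deficient", call. = FALSE)
  coefs <- qr.coef(qx, y)
  betas <- coefs[attr(design, "trial_cols"), , drop = FALSE]
  if (any(!is.finite(betas)))
    stop("non-finite beta estimates", call. = FALSE)
  labels4 <- attr(design, "conditions")
  coords <- which(array(mvec, d[1:3]), arr.ind = TRUE) - 1L
  dimnames(coords) <- NULL
  structure(list(betas = unname(betas), labels4 = labels4,
                 labels2 = relabel_two_class(labels4),
                 voxel_coords = coords, grid_shape = as.integer(d[1:3]),
                 voxel_size_mm = run$voxel_size_mm),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("Beta series: %d trials x %d voxels\n", nrow(x$betas),
              ncol(x$betas)))
  print(table(x$labels4))
  invisible(x)
}

#' Collapse four location labels into two body-part labels
#'
#' Deterministic relabeling for the binary task: Arm A and Arm B become
#' "upper limb", Leg A and Leg B become "lower limb".
#'
#' @param labels4 Character vector of condition labels.
#' @param map Named character vector mapping each known condition to its
#'   body part.
#' @return Character vector of body-part labels.
#' @examples
#' relabel_two_class(c("Arm A", "Leg B", "Arm B", "Leg A"))
#' @export
relabel_two_class <- function(labels4,
                              map = c("Arm A" = "upper limb",
                                      "Arm B" = "upper limb",
                                      "Leg A" = "lower limb",
                                      "Leg B" = "lower limb")) {
  labels4 <- as.character(labels4)
  unknown <- setdiff(unique(labels4), names(map))
  if (length(unknown))
    stop(sprintf("unknown condition label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  unname(map[labels4])
}
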