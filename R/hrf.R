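#' Gamma hemodynamic response function
#'
#' Single-gamma HRF in the AFNI GAM parameterization,
#' \deqn{h(t) = (t / (p q))^p \exp(p - t/q),}
#' which has unit peak at \eqn{t = p q} (about 4.70 s at the defaults
#' p = 8.6, q = 0.547) and h(0) = 0.
#'
#' @param p Gamma shape (dimensionless).
#' @param q Gamma time-scale in seconds.
#' @param duration_s Support length of the sampled kernel in seconds.
#' @return `hrf_spec()` returns a parameter object of class `hrf_spec`;
#'   `gamma_hrf()` returns the kernel sampled at `0, dt, 2 dt, ...` up to
#'   `duration_s` (inclusive).
#' @examples
#' h <- gamma_hrf(hrf_spec(), dt = 0.1)
#' max(h)  # 1 at t = p * q
#' @export
hrf_spec <- function(p = 8.6, q = 0.547, duration_s = 20) {
  stop_if_not_scalar_pos(p, "p")
  stop_if_not_scalar_pos(q, "q")
  stop_if_not_scalar_pos(duration_s, "duration_s")
  structure(list(p = p, q = q, duration_s = duration_s), class = "hrf_spec")
}

#' @rdname hrf_spec
#' @param spec An `hrf_spec`.
#' @param dt Sampling interval in seconds (e.g. the TR, or a fine grid step).
#' @export
gamma_hrf <- function(spec = hrf_spec(), dt) {
  stopifnot(inherits(spec, "hrf_spec"))
  stop_if_not_scalar_pos(dt, "dt")
  t <- seq(0, spec$duration_s, by = dt)
  h <- (t / (spec$p * spec$q))^spec$p * exp(spec$p - t / spec$q)
  h[1] <- 0  # limit of the formula at t = 0 (p > 0)
  h
}

# Trial-wise regressors sampled at the volume times: each trial's boxcar
# (amplitude 1, length = event duration) is convolved with the gamma HRF on
# a fine time grid (dt seconds, Riemann-scaled so the result approximates
# the continuous convolution), then read out at t = 0, TR, 2 TR, ...
trial_regressors <- function(events, n_volumes, tr_s, hrf = hrf_spec(),
                             dt = 0.1) {
  run_len <- n_volumes * tr_s
  if (any(events$onset < 0) ||
      any(events$onset + events$duration > run_len + 1e-9))
    stop("events fall outside the run", call. = FALSE)
  nt <- ceiling(run_len / dt) + 1L
  tfine <- (seq_len(nt) - 1L) * dt
  h <- gamma_hrf(hrf, dt)
  x <- matrix(0, n_volumes, nrow(events))
  vol_idx <- round((seq_len(n_volumes) - 1L) * tr_s / dt) + 1L
  for (i in seq_len(nrow(events))) {
    box <- as.numeric(tfine >= events$onset[i] - 1e-9 &
                      tfine < events$onset[i] + events$duration[i] - 1e-9)
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(nt)] * dt
    x[, i] <- conv[vol_idx]
  }
  x
}

# Legendre polynomials P_0..P_order evaluated on n points spanning [-1, 1],
# by the three-term recurrence; used as slow drift nuisance regressors.
legendre_drift <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  out <- matrix(0, n, order + 1L)
  out[, 1] <- 1
  if (order >= 1) out[, 2] <- x
  if (order >= 2)
    for (k in 2:order)
      out[, k + 1] <- ((2 * k - 1) * x * out[, k] - (k - 1) * out[, k - 1]) / k
  out
}

#' Build the trial-wise (beta-series) design matrix
#'
#' One column per trial -- the trial's boxcar convolved with the gamma HRF,
#' sampled at the TR -- followed by an intercept and Legendre drift columns
#' up to `drift_order`. This is the LS-A convention: all trials are
#' estimated jointly in a single model.
#'
#' @param events An `event_table`.
#' @param n_volumes Number of volumes in the run.
#' @param tr_s Repetition time in seconds.
#' @param hrf An [hrf_spec()].
#' @param drift_order Highest Legendre polynomial order (0 = intercept only).
#' @param dt Fine convolution grid step in seconds.
#' @return A `design_matrix`: numeric matrix `n_volumes` x
#'   `(n_trials + drift_order + 1)` with attributes `trial_cols`
#'   (column indices of trials) and `conditions` (trial condition labels).
#' @export
build_design_matrix <- function(events, n_volumes, tr_s, hrf = hrf_spec(),
                                drift_order = 1, dt = 0.1) {
  stopifnot(is.data.frame(events), nrow(events) >= 1)
  stop_if_not_scalar_pos(n_volumes, "n_volumes")
  stop_if_not_scalar_pos(tr_s, "tr_s")
  stop_if_not_scalar_pos(drift_order, "drift_order", strict = FALSE)
  xt <- trial_regressors(events, n_volumes, tr_s, hrf, dt)
  xn <- legendre_drift(n_volumes, drift_order)
  x <- cbind(xt, xn)
  colnames(x) <- c(sprintf("trial_%02d", seq_len(nrow(events))),
                   "intercept",
                   if (drift_order >= 1) sprintf("drift_%d", seq_len(drift_order)))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop(sprintf("design matrix is rank deficient; offending column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  structure(x, trial_cols = seq_len(nrow(events)),
            conditions = as.character(events$trial_type),
            tr_s = tr_s, class = c("design_matrix", "matrix", "array"))
}
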