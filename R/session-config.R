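#' Session configuration for an event-related stimulation run
#'
#' Bundles the acquisition and design parameters of one stimulation scan:
#' four stimulus conditions (two arm sites, two leg sites), five trials per
#' condition, 5-s stimulation events, jittered onset-to-onset inter-trial
#' intervals with mean 14.92 s and SD 1.66 s constrained to 13--17 s,
#' a repetition time of 2 s and 3-mm isotropic voxels on a 20x20x20 grid.
#'
#' The inter-trial interval (ITI) is defined onset-to-onset, so twenty
#' ~15-s trials fill a five-minute stimulation scan. By default jitter is
#' drawn from three discrete levels (13, 15, 17 s) whose sampling weights
#' are solved in closed form so that the jitter distribution has exactly
#' the configured mean and SD; see [solve_iti_weights()]. No distribution
#' supported on an interval of width 4 s and unimodal can reach an SD of
#' 1.66 s (the uniform limit is 4/sqrt(12) = 1.15 s), which is why a
#' discrete-level scheme -- standard in event-related designs -- is the
#' default. A truncated-normal alternative (`iti_method = "truncnorm"`) is
#' provided; its realized SD is necessarily smaller than the nominal one.
#'
#' @param n_conditions Number of stimulus conditions.
#' @param condition_names Labels, one per condition.
#' @param trials_per_condition Trials per condition per run.
#' @param stim_duration_s Stimulus duration in seconds.
#' @param iti_mean_s,iti_sd_s Target mean and SD of the onset-to-onset ITI
#'   in seconds.
#' @param iti_range_s Closed interval (length-2 numeric) containing all ITIs.
#' @param iti_method `"levels"` (discrete jitter levels, default) or
#'   `"truncnorm"` (normal truncated to `iti_range_s`).
#' @param iti_levels Jitter levels in seconds used when
#'   `iti_method = "levels"`; exactly three levels so the weights matching
#'   mean and SD are uniquely determined.
#' @param tr_s Repetition time (volume spacing) in seconds.
#' @param grid_shape Integer vector of voxel counts per axis.
#' @param voxel_size_mm Voxel size per axis in millimetres.
#' @param initial_rest_s Rest before the first trial onset, seconds.
#' @param seed Integer seed controlling schedule randomization.
#' @return An object of class `session_config` (a validated list).
#' @examples
#' cfg <- session_config(seed = 1)
#' ev <- generate_event_schedule(cfg)
#' table(ev$trial_type)
#' @export
session_config <- function(n_conditions = 4,
                           condition_names = c("Arm A", "Arm B",
                                               "Leg A", "Leg B"),
                           trials_per_condition = 5,
                           stim_duration_s = 5,
                           iti_mean_s = 14.92,
                           iti_sd_s = 1.66,
                           iti_range_s = c(13, 17),
                           iti_method = c("levels", "truncnorm"),
                           iti_levels = c(13, 15, 17),
                           tr_s = 2.0,
                           grid_shape = c(20L, 20L, 20L),
                           voxel_size_mm = c(3, 3, 3),
                           initial_rest_s = 10,
                           seed = NULL) {
  iti_method <- match.arg(iti_method)
  stop_if_not_scalar_pos(n_conditions, "n_conditions")
  stop_if_not_scalar_pos(trials_per_condition, "trials_per_condition")
  stop_if_not_scalar_pos(stim_duration_s, "stim_duration_s")
  stop_if_not_scalar_pos(tr_s, "tr_s")
  stop_if_not_scalar_pos(iti_sd_s, "iti_sd_s", strict = FALSE)
  stop_if_not_scalar_pos(initial_rest_s, "initial_rest_s", strict = FALSE)
  if (length(condition_names) != n_conditions)
    stop("'condition_names' must have one entry per condition", call. = FALSE)
  if (anyDuplicated(condition_names))
    stop("'condition_names' must be unique", call. = FALSE)
  if (length(iti_range_s) != 2L || diff(iti_range_s) < 0)
    stop("'iti_range_s' must be an increasing length-2 interval", call. = FALSE)
  if (iti_mean_s < iti_range_s[1] || iti_mean_s > iti_range_s[2])
    stop("'iti_range_s' must contain 'iti_mean_s'", call. = FALSE)
  if (iti_range_s[1] < stim_duration_s)
    stop("lower ITI bound below the stimulus duration: events would overlap",
         call. = FALSE)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("'grid_shape' must be three positive voxel counts", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three positive sizes", call. = FALSE)
  if (iti_method == "levels" && iti_sd_s > 0) {
    if (length(iti_levels) != 3L)
      stop("'iti_levels' must hold exactly three levels", call. = FALSE)
    if (any(iti_levels < iti_range_s[1]) || any(iti_levels > iti_range_s[2]))
      stop("'iti_levels' must lie inside 'iti_range_s'", call. = FALSE)
    # fails early if the requested moments are unreachable on these levels
    solve_iti_weights(iti_levels, iti_mean_s, iti_sd_s)
  }
  structure(list(
    n_conditions = as.integer(n_conditions),
    condition_names = as.character(condition_names),
    trials_per_condition = as.integer(trials_per_condition),
    n_trials = as.integer(n_conditions * trials_per_condition),
    stim_duration_s = stim_duration_s,
    iti_mean_s = iti_mean_s, iti_sd_s = iti_sd_s,
    iti_range_s = as.numeric(iti_range_s),
    iti_method = iti_method, iti_levels = as.numeric(iti_levels),
    tr_s = tr_s,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    initial_rest_s = initial_rest_s,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("Session configuration\n")
  cat(sprintf("  %d conditions x %d trials (%s)\n", x$n_conditions,
              x$trials_per_condition, paste(x$condition_names, collapse = ", ")))
  cat(sprintf("  stimulus %.3g s; ITI %.4g +/- %.3g s on [%g, %g] (%s)\n",
              x$stim_duration_s, x$iti_mean_s, x$iti_sd_s,
              x$iti_range_s[1], x$iti_range_s[2], x$iti_method))
  cat(sprintf("  TR %.3g s; grid %s; voxel %s mm\n", x$tr_s,
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Solve discrete jitter-level weights matching target moments
#'
#' Given three jitter levels \eqn{l_1 < l_2 < l_3} and target mean \eqn{m}
#' and standard deviation \eqn{s}, solves the 3x3 linear system
#' \deqn{\sum w_i = 1, \quad \sum w_i l_i = m, \quad \sum w_i l_i^2 = s^2 + m^2}
#' for the sampling weights. Errors if any weight falls outside \[0, 1\]
#' (the requested moments are then unreachable on these levels).
#'
#' @param levels Three distinct jitter levels (seconds).
#' @param mean_s,sd_s Target mean and SD (seconds).
#' @return Numeric weight vector of length 3 summing to 1.
#' @examples
#' w <- solve_iti_weights(c(13, 15, 17), 14.92, 1.66)
#' sum(w * c(13, 15, 17))                      # 14.92
#' sqrt(sum(w * (c(13, 15, 17) - 14.92)^2))    # 1.66
#' @export
solve_iti_weights <- function(levels, mean_s, sd_s) {
  stopifnot(length(levels) == 3L, !anyDuplicated(levels))
  a <- rbind(rep(1, 3), levels, levels^2)
  b <- c(1, mean_s, sd_s^2 + mean_s^2)
  w <- as.numeric(solve(a, b))
  if (any(w < -1e-12) || any(w > 1 + 1e-12))
    stop(sprintf(paste0("no probability weights on levels (%s) give mean %.4g",
                        " and SD %.4g"),
                 paste(levels, collapse = ", "), mean_s, sd_s), call. = FALSE)
  pmin(pmax(w, 0), 1)
}
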