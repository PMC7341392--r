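#' Generate a randomized event schedule for one run
#'
#' Produces one row per trial with strictly increasing onsets. The condition
#' sequence is a seeded random permutation containing exactly
#' `trials_per_condition` occurrences of each condition; onset-to-onset
#' inter-trial intervals are drawn per `config$iti_method` (discrete jitter
#' levels by default, or a normal truncated to `iti_range_s`). With
#' `iti_sd_s = 0` every interval equals `iti_mean_s` exactly.
#'
#' @param config A [session_config()].
#' @return A `data.frame` of class `event_table` with columns `onset`,
#'   `duration`, `trial_type` (seconds; BIDS events dialect).
#' @examples
#' ev <- generate_event_schedule(session_config(seed = 7))
#' diff(ev$onset)  # jittered ITIs in 13..17 s
#' @export
generate_event_schedule <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials
  with_seed(config$seed, {
    cond <- sample(rep(config$condition_names, config$trials_per_condition))
    itis <- draw_itis(n - 1L, config)
  })
  onsets <- config$initial_rest_s + cumsum(c(0, itis))
  ev <- data.frame(onset = onsets,
                   duration = rep(config$stim_duration_s, n),
                   trial_type = cond,
                   stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

# Draw n onset-to-onset intervals under the configured jitter scheme.
draw_itis <- function(n, config) {
  if (n == 0L) return(numeric(0))
  if (config$iti_sd_s == 0) return(rep(config$iti_mean_s, n))
  switch(config$iti_method,
    levels = {
      w <- solve_iti_weights(config$iti_levels, config$iti_mean_s,
                             config$iti_sd_s)
      sample(config$iti_levels, n, replace = TRUE, prob = w)
    },
    truncnorm = {
      lo <- stats::pnorm(config$iti_range_s[1], config$iti_mean_s,
                         config$iti_sd_s)
      hi <- stats::pnorm(config$iti_range_s[2], config$iti_mean_s,
                         config$iti_sd_s)
      stats::qnorm(stats::runif(n, lo, hi), config$iti_mean_s, config$iti_sd_s)
    })
}

#' Write / read a BIDS-style events table
#'
#' Tab-separated with header `onset duration trial_type`; onsets and
#' durations in seconds, written in 6-decimal fixed point so tables
#' round-trip losslessly at that precision.
#'
#' @param events An `event_table` data frame.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns an `event_table`.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  out <- data.frame(onset = sprintf("%.6f", events$onset),
                    duration = sprintf("%.6f", events$duration),
                    trial_type = events$trial_type)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop(sprintf("malformed events file '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  onset <- suppressWarnings(as.numeric(ev$onset))
  duration <- suppressWarnings(as.numeric(ev$duration))
  bad <- which(!is.finite(onset) | !is.finite(duration))
  if (length(bad))
    stop(sprintf("malformed events file '%s': non-numeric onset/duration at line %d",
                 path, bad[1] + 1L), call. = FALSE)
  ev <- data.frame(onset = onset, duration = duration,
                   trial_type = ev$trial_type, stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}
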