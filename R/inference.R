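#' Permutation null distribution of decoding accuracy
#'
#' For each permutation the whole trial-label vector is uniformly shuffled
#' (preserving class counts), folds are re-stratified, and the full
#' cross-validated decoding pipeline -- within-fold F-score selection,
#' classifier training, held-out prediction -- is re-run; its mean accuracy
#' is recorded. Permutation `i` uses the derived seed `seed + i`, so the
#' first `k` entries are identical for any `n_perm >= k` at the same seed.
#'
#' @param bs A beta series (see [cross_validated_decode()]).
#' @param task `"four_class"` or `"two_class"`.
#' @param cfg A [decoder_config()].
#' @param n_perm Number of permutations.
#' @param seed Integer base seed.
#' @param select Apply within-fold feature selection (default TRUE).
#' @return Object of class `permutation_null`: list with `null_accuracies`
#'   (length `n_perm`), `n_perm`, `seed`, `task`.
#' @export
permutation_null <- function(bs, task = c("four_class", "two_class"),
                             cfg = decoder_config(), n_perm = 1000,
                             seed = NULL, select = TRUE) {
  task <- match.arg(task)
  stop_if_not_scalar_pos(n_perm, "n_perm")
  y <- if (task == "four_class") bs$labels4 else bs$labels2
  x <- bs$betas
  acc <- numeric(n_perm)
  cfg_i <- cfg
  for (i in seq_len(n_perm)) {
    si <- derive_seed(seed, i)
    perm <- with_seed(si, sample.int(length(y)))
    cfg_i$seed <- si
    acc[i] <- cv_decode_accuracy(x, y[perm], cfg_i, select = select)
  }
  structure(list(null_accuracies = acc, n_perm = as.integer(n_perm),
                 seed = seed, task = task), class = "permutation_null")
}

#' Permutation test of an observed decoding accuracy
#'
#' Convenience wrapper: decodes with the true labels, builds the
#' permutation null with [permutation_null()], and returns the smoothed
#' empirical p value.
#'
#' @inheritParams permutation_null
#' @return List with `observed` (the [cross_validated_decode()] result),
#'   `null` (a `permutation_null`), and `p`.
#' @export
permutation_test <- function(bs, task = c("four_class", "two_class"),
                             cfg = decoder_config(), n_perm = 1000,
                             seed = NULL, select = TRUE) {
  task <- match.arg(task)
  obs <- cross_validated_decode(bs, task, cfg, select = select)
  null <- permutation_null(bs, task, cfg, n_perm, seed, select = select)
  list(observed = obs, null = null,
       p = empirical_p(obs$accuracy, null$null_accuracies))
}

#' Smoothed empirical p value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` -- the add-one
#' (Phipson-Smyth) convention, so a Monte-Carlo p value is never zero and
#' ties count against the observation.
#'
#' @param observed Observed statistic.
#' @param null_accuracies Vector of null statistics.
#' @return The empirical p value.
#' @examples
#' empirical_p(0.25, c(0.2, 0.25, 0.3))  # (1 + 2) / (1 + 3) = 0.75
#' @export
empirical_p <- function(observed, null_accuracies) {
  if (!length(null_accuracies)) stop("empty null distribution", call. = FALSE)
  (1 + sum(null_accuracies >= observed)) / (1 + length(null_accuracies))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with a rejection mask
#' at the given q threshold: the adjusted value for the i-th smallest p is
#' `min over j >= i of m p_(j) / j`, capped at 1.
#'
#' @param p_values Vector of p values in \[0, 1\].
#' @param q_threshold Significance threshold on the adjusted values.
#' @return List with `q` (adjusted values), `reject` (logical mask,
#'   `q <= q_threshold`), `q_threshold`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.5))$reject  # TRUE TRUE TRUE FALSE
#' @export
fdr_bh <- function(p_values, q_threshold = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, reject = !is.na(q) & q <= q_threshold,
       q_threshold = q_threshold)
}

#' Group-level test of decoding accuracy against chance
#'
#' One-sample t test of per-subject accuracies minus the chance level, or
#' -- when a second accuracy vector is supplied -- a paired t test between
#' the two conditions. Zero variance across subjects leaves the t-based p
#' undefined; it is flagged rather than reported as significant.
#'
#' @param accuracies Per-subject accuracies.
#' @param chance Chance level (ignored for the paired variant).
#' @param paired_with Optional second accuracy vector for a paired test.
#' @param alternative Test sidedness, as in [stats::t.test()].
#' @return List with `t`, `df`, `p`, `mean`, `degenerate` (TRUE when the
#'   contrast has zero variance, in which case `p` is NA).
#' @export
group_accuracy_test <- function(accuracies, chance = NULL, paired_with = NULL,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(accuracies) < 2)
    stop("group test needs at least two subjects", call. = FALSE)
  d <- if (is.null(paired_with)) {
    if (is.null(chance)) stop("'chance' required for the one-sample test",
                              call. = FALSE)
    accuracies - chance
  } else {
    if (length(paired_with) != length(accuracies))
      stop("paired vectors must have equal length", call. = FALSE)
    accuracies - paired_with
  }
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1L,
                p = NA_real_, mean = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(d), degenerate = FALSE)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null (%s): %d permutations, mean %.4f, sd %.4f\n",
              x$task, x$n_perm, mean(x$null_accuracies),
              stats::sd(x$null_accuracies)))
  invisible(x)
}

#' @export
plot.permutation_null <- function(x, observed = NULL, ...) {
  graphics::hist(x$null_accuracies, breaks = 30, col = "orange",
                 main = sprintf("Null accuracies (%s)", x$task),
                 xlab = "accuracy", ...)
  if (!is.null(observed)) graphics::abline(v = observed, col = "red", lwd = 2)
  invisible(x)
}
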