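#' Decoder configuration
#'
#' Settings for cross-validated location decoding: stratified k-fold CV
#' (default 5 folds), within-fold ANOVA-F percentile feature selection
#' (default top 10 percent of voxels), and a linear-kernel support-vector
#' classifier (libsvm via \pkg{e1071}, native one-vs-one for more than two
#' classes) with fixed regularization `cost` (no nested tuning).
#'
#' @param n_folds Number of cross-validation folds.
#' @param selection_percentile Percent of voxels kept by F-score selection
#'   (0 < percentile <= 100).
#' @param cost SVM regularization strength C.
#' @param seed Integer seed for fold shuffling.
#' @return Object of class `decoder_config`.
#' @export
decoder_config <- function(n_folds = 5, selection_percentile = 10,
                           cost = 1, seed = NULL) {
  stop_if_not_scalar_pos(n_folds, "n_folds")
  stop_if_not_scalar_pos(cost, "cost")
  if (!is.numeric(selection_percentile) || selection_percentile <= 0 ||
      selection_percentile > 100)
    stop("'selection_percentile' must lie in (0, 100]", call. = FALSE)
  if (n_folds < 2) stop("'n_folds' must be at least 2", call. = FALSE)
  structure(list(n_folds = as.integer(n_folds),
                 selection_percentile = selection_percentile,
                 cost = cost,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "decoder_config")
}

# Vectorized one-way ANOVA F statistic per column of X.
# Constant columns (zero between- and within-class variance) get F = 0;
# columns that separate classes perfectly (zero within-class variance,
# positive between) get F = Inf.
f_oneway_stat <- function(x, y) {
  if (!is.factor(y)) y <- factor(y)
  n <- nrow(x)
  k <- nlevels(y)
  ng <- as.numeric(table(y))
  gs <- rowsum(x, y)                       # class sums, k x V
  gm <- gs / ng
  tot <- colSums(x)
  ssb <- colSums(gm^2 * ng) - tot^2 / n
  sst <- colSums(x^2) - tot^2 / n
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  eps <- 1e-12 * pmax(1, sst)
  f[ssw <= eps & ssb <= eps] <- 0
  f[ssw <= eps & ssb > eps] <- Inf
  f
}

#' ANOVA-F percentile feature selection
#'
#' Computes the one-way ANOVA F statistic (between-class over within-class
#' mean square) for every voxel and returns the indices of the
#' `ceiling(percentile/100 * V)` voxels with the highest F. Ties are
#' broken deterministically in favour of the lower index. Voxels constant
#' across all trials have F = 0 and are never selected ahead of any voxel
#' with positive F.
#'
#' @param x Trials x voxels matrix.
#' @param y Class labels, one per trial (at least two classes, at least
#'   two trials per class).
#' @param percentile Percent of voxels to keep.
#' @return Integer vector of selected voxel indices, in increasing order.
#' @export
fscore_select <- function(x, y, percentile = 10) {
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) < 2)
    stop("feature selection needs at least two classes", call. = FALSE)
  if (any(tabulate(y) < 2))
    stop("feature selection needs at least two trials per class", call. = FALSE)
  if (percentile <= 0 || percentile > 100)
    stop("'percentile' must lie in (0, 100]", call. = FALSE)
  v <- ncol(x)
  n_keep <- min(v, as.integer(ceiling(percentile / 100 * v)))
  f <- f_oneway_stat(x, y)
  # stable radix sort: ties broken in favour of the lower index
  ord <- sort.list(-f, method = "radix")
  sort(ord[seq_len(n_keep)])
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `n_folds` folds so that per-class counts
#' across folds differ by at most one; class members are shuffled with the
#' given seed before assignment, so the split is deterministic given the
#' seed.
#'
#' @param y Class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per trial.
#' @export
stratified_folds <- function(y, n_folds = 5, seed = NULL) {
  if (!is.factor(y)) y <- factor(y)
  cnt <- table(y)
  if (any(cnt < n_folds))
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                 names(cnt)[which.min(cnt)], min(cnt), n_folds), call. = FALSE)
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      members <- which(y == lv)
      members <- members[sample.int(length(members))]
      folds[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  folds
}

# Lean one-fold fit/predict used by both whole-brain and searchlight paths.
# Returns predicted labels for the test rows (and decision scores for
# binary problems, oriented so that larger favours the second factor level).
svm_fold <- function(xtr, ytr, xte, cost, scores = FALSE) {
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                    scale = FALSE, fitted = FALSE)
  if (!scores) return(predict(fit, xte))
  pr <- predict(fit, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos <- levels(ytr)[2]
  # column name "A/B": positive decision value favours A
  first <- sub("/.*$", "", colnames(dv)[1])
  s <- if (first == pos) dv[, 1] else -dv[, 1]
  list(pred = pr, score = as.numeric(s))
}

# Lean CV accuracy: identical folds, selection and classifier as
# cross_validated_decode, without prediction bookkeeping or metrics.
# Used in permutation loops where only the mean accuracy is needed.
cv_decode_accuracy <- function(x, y, cfg, select = TRUE) {
  if (!is.factor(y)) y <- factor(y)
  folds <- stratified_folds(y, cfg$n_folds, cfg$seed)
  truth <- as.character(y)
  correct <- 0L
  for (f in seq_len(cfg$n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    cols <- if (select)
      fscore_select(x[tr, , drop = FALSE], y[tr], cfg$selection_percentile)
    else seq_len(ncol(x))
    # stratified folds leave every class represented in the training rows
    pr <- svm_fold(x[tr, cols, drop = FALSE], y[tr],
                   x[te, cols, drop = FALSE], cfg$cost)
    correct <- correct + sum(as.character(pr) == truth[te])
  }
  correct / length(y)
}

#' Cross-validated decoding of stimulated locations
#'
#' Runs stratified k-fold cross-validation of the linear support-vector
#' classifier over a beta series. Inside every fold, ANOVA-F percentile
#' feature selection is fitted on the training rows only, the classifier
#' is trained on the selected voxels, and the held-out rows are predicted;
#' no information from test rows enters selection or training. Pooled
#' predictions across folds feed the metric suite.
#'
#' @param bs A [fit_beta_series()] result, or any list with `betas`,
#'   `labels4`, `labels2`.
#' @param task `"four_class"` (four locations) or `"two_class"` (upper vs
#'   lower limb).
#' @param cfg A [decoder_config()].
#' @param select Apply within-fold feature selection (TRUE for the
#'   whole-brain analysis; the searchlight path sets FALSE).
#' @return Object of class `decoding_result`: list with `predictions`
#'   (data frame: trial, fold, truth, pred, score), `accuracy`, `metrics`
#'   (see [compute_metrics()]), `confusion`, `selected` (per-fold selected
#'   voxel indices), `task`, `config`.
#' @export
cross_validated_decode <- function(bs, task = c("four_class", "two_class"),
                                   cfg = decoder_config(), select = TRUE) {
  task <- match.arg(task)
  x <- bs$betas
  y <- factor(if (task == "four_class") bs$labels4 else bs$labels2)
  folds <- stratified_folds(y, cfg$n_folds, cfg$seed)
  n <- length(y)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  score <- rep(NA_real_, n)
  binary <- nlevels(y) == 2
  selected <- vector("list", cfg$n_folds)
  for (f in seq_len(cfg$n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    cols <- if (select)
      fscore_select(x[tr, , drop = FALSE], y[tr], cfg$selection_percentile)
    else seq_len(ncol(x))
    selected[[f]] <- cols
    out <- svm_fold(x[tr, cols, drop = FALSE], droplevels(y[tr]),
                    x[te, cols, drop = FALSE], cfg$cost, scores = binary)
    if (binary) {
      pred[te] <- as.character(out$pred)
      score[te] <- out$score
    } else pred[te] <- as.character(out)
  }
  metrics <- compute_metrics(y, pred, if (binary) score else NULL, task)
  structure(list(
    predictions = data.frame(trial = seq_len(n), fold = folds,
                             truth = as.character(y), pred = as.character(pred),
                             score = score),
    accuracy = metrics$accuracy, metrics = metrics,
    confusion = metrics$confusion, selected = selected,
    task = task, config = cfg), class = "decoding_result")
}

#' Decoding performance metrics
#'
#' Accuracy, macro-averaged precision/recall/F1, the confusion matrix
#' (truth in rows, prediction in columns), and -- for binary tasks with
#' decision scores -- the ROC-AUC from the pooled cross-validated scores.
#' ROC-AUC is not defined for more than two classes and is omitted (with a
#' message) if requested there. Classes never predicted contribute
#' precision 0 to the macro average.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param scores Pooled decision scores for the positive (second-level)
#'   class, or NULL.
#' @param task Task name recorded in the output.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `roc_auc`
#'   (NA unless binary with scores), `confusion`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL, task = "") {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / colSums(cm)
  prec[!is.finite(prec)] <- 0
  rec <- diag(cm) / rowSums(cm)
  rec[!is.finite(rec)] <- 0
  f1 <- 2 * prec * rec / (prec + rec)
  f1[!is.finite(f1)] <- 0
  auc <- NA_real_
  if (!is.null(scores)) {
    if (nlevels(truth) != 2) {
      message("ROC-AUC is only computed for two-class tasks; skipping")
    } else {
      roc <- pROC::roc(response = truth, predictor = as.numeric(scores),
                       levels = levels(truth), direction = "<", quiet = TRUE)
      auc <- as.numeric(pROC::auc(roc))
    }
  }
  list(accuracy = acc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), roc_auc = auc, confusion = cm, task = task)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result (%s): accuracy %.3f", x$task, x$accuracy))
  if (!is.na(x$metrics$roc_auc))
    cat(sprintf(", ROC-AUC %.3f", x$metrics$roc_auc))
  cat(sprintf("\n  macro precision %.3f, recall %.3f, F1 %.3f\n",
              x$metrics$precision, x$metrics$recall, x$metrics$f1))
  print(x$confusion)
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  cm <- unclass(x$confusion)
  graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)), t(cm[rev(seq_len(nrow(cm))), ]),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = sprintf("Confusion (%s)", x$task), ...)
  graphics::axis(1, seq_len(ncol(cm)), colnames(cm))
  graphics::axis(2, seq_len(nrow(cm)), rev(rownames(cm)))
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm)))
    graphics::text(j, nrow(cm) - i + 1, cm[i, j])
  invisible(x)
}
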