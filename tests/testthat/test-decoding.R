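test_that("F-score selection matches a brute-force ANOVA oracle", {
  fx <- make_beta_fixture(31, n_voxels = 100, signal_voxels = 1:10,
                          amplitude = 3, sigma = 1)
  # oracle: per-voxel one-way ANOVA F from stats::oneway.test, ranked
  f_oracle <- vapply(seq_len(100), function(j)
    stats::oneway.test(fx$betas[, j] ~ factor(fx$labels4),
                       var.equal = TRUE)$statistic, numeric(1))
  f_pkg <- somadecode:::f_oneway_stat(fx$betas, fx$labels4)
  expect_equal(unname(f_pkg), unname(f_oracle), tolerance = 1e-10)
  sel <- fscore_select(fx$betas, fx$labels4, percentile = 10)
  expect_identical(sel, sort(order(-f_oracle)[1:10]))
  expect_identical(sel, 1:10)  # the planted informative voxels
})

test_that("selection handles identity, ceiling and degenerate cases", {
  fx <- make_beta_fixture(32, n_voxels = 30)
  expect_identical(fscore_select(fx$betas, fx$labels4, 100), 1:30)
  # ceiling rule: 10% of 30 voxels -> 3
  expect_length(fscore_select(fx$betas, fx$labels4, 10), 3L)
  expect_length(fscore_select(fx$betas, fx$labels4, 11), 4L)
  # constant voxel gets F = 0, never selected ahead of positive-F voxels
  x <- fx$betas
  x[, 5] <- 7
  f <- somadecode:::f_oneway_stat(x, fx$labels4)
  expect_equal(unname(f[5]), 0)
  expect_false(5L %in% fscore_select(x, fx$labels4, 90))
  expect_error(fscore_select(x, rep("a", 20)), "two classes")
})

test_that("stratified folds partition trials and balance classes", {
  y4 <- rep(c("Arm A", "Arm B", "Leg A", "Leg B"), each = 5)
  f <- stratified_folds(y4, 5, seed = 3)
  expect_setequal(f, 1:5)
  for (k in 1:5) {
    te <- which(f == k)
    expect_length(te, 4L)
    expect_true(all(table(y4[te]) == 1L))
  }
  y2 <- rep(c("u", "l"), each = 10)
  f2 <- stratified_folds(y2, 5, seed = 3)
  expect_true(all(table(y2, f2) == 2L))
  expect_identical(f, stratified_folds(y4, 5, seed = 3))
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 17)), 5),
               "fewer members")
})

test_that("strong multivoxel signal is decoded nearly perfectly", {
  out <- make_bs(41, grid = c(10L, 10L, 10L), shared = 1.5, unique = 1.5,
                 sigma = 0.5)
  res <- cross_validated_decode(out$bs, "four_class",
                                decoder_config(seed = 42))
  expect_gte(res$accuracy, 0.9)
  res2 <- cross_validated_decode(out$bs, "two_class",
                                 decoder_config(seed = 42))
  expect_gte(res2$accuracy, 0.9)
  expect_gte(res2$metrics$roc_auc, 0.9)
})

test_that("decoding results are deterministic and conserve trials", {
  fx <- make_beta_fixture(44, n_voxels = 60, signal_voxels = 1:5,
                          amplitude = 1, sigma = 1)
  cfg <- decoder_config(seed = 9)
  r1 <- cross_validated_decode(fx, "four_class", cfg)
  r2 <- cross_validated_decode(fx, "four_class", cfg)
  expect_identical(r1, r2)
  cm <- r1$confusion
  expect_equal(unname(rowSums(cm)), rep(5, 4), ignore_attr = TRUE)
  expect_equal(sum(cm), 20)
  expect_equal(r1$accuracy, sum(diag(cm)) / sum(cm))
  # every trial predicted exactly once across folds
  expect_setequal(r1$predictions$trial, 1:20)
  expect_false(any(is.na(r1$predictions$pred)))
})

test_that("selection and training never see held-out rows", {
  fx <- make_beta_fixture(45, n_voxels = 80, signal_voxels = 1:8,
                          amplitude = 1.5, sigma = 1)
  cfg <- decoder_config(seed = 13)
  res <- cross_validated_decode(fx, "four_class", cfg)
  folds <- res$predictions$fold
  y <- factor(fx$labels4)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    # recompute selection + model from training rows alone; test labels
    # cannot enter because they are never passed
    sel <- fscore_select(fx$betas[tr, ], y[tr], cfg$selection_percentile)
    expect_identical(res$selected[[f]], sel)
    fit <- e1071::svm(fx$betas[tr, sel, drop = FALSE], droplevels(y[tr]),
                      kernel = "linear", cost = 1, scale = FALSE)
    pr <- as.character(predict(fit, fx$betas[te, sel, drop = FALSE]))
    expect_identical(res$predictions$pred[te], pr)
  }
})

test_that("mean accuracy rises with the signal-to-noise ratio", {
  mean_acc <- function(amp) {
    mean(vapply(1:4, function(s) {
      out <- make_bs(100 + s, grid = c(8L, 8L, 8L), shared = 0, unique = amp,
                     sigma = 1, roi = small_roi(c(8L, 8L, 8L)))
      cross_validated_decode(out$bs, "four_class",
                             decoder_config(seed = s))$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0, 1, 3), mean_acc, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("metrics match hand-computed values on a fixed prediction table", {
  # 8 binary trials, 6 correct, one error per class
  truth <- c("l", "l", "l", "l", "u", "u", "u", "u")
  pred  <- c("l", "l", "l", "u", "u", "u", "u", "l")
  m <- compute_metrics(truth, pred)
  expect_equal(m$accuracy, 0.75)
  # by hand: precision(l) = 3/4, precision(u) = 3/4; recall same
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(as.numeric(m$confusion), c(3, 1, 1, 3))

  mp <- compute_metrics(truth, truth)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$f1, 1)
  expect_true(all(m$confusion >= 0))

  # anti-classifier: all labels flipped, scores negated
  scores <- c(-1, -2, -3, -4, 1, 2, 3, 4)  # favour "u" when positive
  flipped <- ifelse(truth == "l", "u", "l")
  mf <- compute_metrics(truth, flipped, scores = -scores)
  expect_equal(mf$accuracy, 0)
  expect_equal(mf$roc_auc, 0)
  m2 <- compute_metrics(truth, truth, scores = scores)
  expect_equal(m2$roc_auc, 1)
})

test_that("ROC-AUC is skipped with a message for multi-class tasks", {
  truth <- rep(c("a", "b", "c", "d"), 2)
  expect_message(m <- compute_metrics(truth, truth, scores = rnorm(8)),
                 "two-class")
  expect_true(is.na(m$roc_auc))
})
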