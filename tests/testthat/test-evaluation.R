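test_that("balanced subsets keep all positives and sample negatives", {
  insts <- small_cohort_instances(150L, seed = 3L)
  y <- instance_labels(insts)
  pos <- which(y == 1L)
  cfg <- eval_config(n_subsets = 5L, seed = 10L)
  subs <- make_balanced_subsets(insts, cfg)
  expect_length(subs, 5L)
  for (s in subs) {
    ys <- instance_labels(s)
    expect_equal(length(s), 2L * length(pos))
    expect_equal(sum(ys), length(pos))
    # the positive set is identical across subsets
    expect_setequal(
      unname(vapply(s[ys == 1L], function(x) x$patient_id, "")),
      unname(vapply(insts[pos], function(x) x$patient_id, "")))
    # negatives are distinct within a subset
    ids <- vapply(s[ys == 0L], function(x) x$patient_id, "")
    expect_equal(anyDuplicated(ids), 0L)
  }
  expect_identical(make_balanced_subsets(insts, cfg),
                   make_balanced_subsets(insts, cfg))
})

test_that("balanced subsets handle degenerate and invalid inputs", {
  insts <- separable_instances(10L)  # 10 pos, 10 neg
  subs <- make_balanced_subsets(insts, eval_config(n_subsets = 3L))
  for (s in subs) expect_equal(length(s), 20L)
  y <- instance_labels(insts)
  expect_error(
    make_balanced_subsets(c(insts[y == 1L], insts[y == 0L][1:3]),
                          eval_config()),
    "undersampling direction")
  expect_error(make_balanced_subsets(insts[y == 1L], eval_config()),
               "both classes")
})

test_that("k-fold splits partition the data with stratification", {
  insts <- separable_instances(10L)  # 20 instances, 10+10
  cfg <- eval_config(n_folds = 5L, seed = 2L)
  splits <- kfold_splits(insts, cfg)
  test_sizes <- vapply(splits, function(s) length(s$test), 1L)
  expect_equal(test_sizes, rep(4L, 5L))
  all_test <- sort(unlist(lapply(splits, function(s) s$test)))
  expect_equal(all_test, 1:20)  # union = dataset, pairwise disjoint
  y <- instance_labels(insts)
  for (s in splits) {
    expect_equal(sum(y[s$test]), 2L)  # 2 positives per fold
    expect_equal(sort(c(s$train, s$test)), 1:20)
  }
  # 23 instances in 5 folds -> sizes {5,5,5,4,4}
  insts23 <- c(insts, separable_instances(2L)[1:3])
  sizes23 <- sort(vapply(kfold_splits(insts23, cfg),
                         function(s) length(s$test), 1L))
  expect_equal(sizes23, c(4L, 4L, 5L, 5L, 5L))
  expect_error(kfold_splits(insts[1:3], cfg), "smaller than n_folds")
})

test_that("confusion metrics match the worked example", {
  # TP=2, FP=1, FN=1, TN=6
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.1, 0.7, 0.2, 0.2, 0.3, 0.1, 0.2, 0.3)
  m <- compute_metrics(labels, probs, threshold = 0.5)
  expect_equal(c(m$TP, m$FP, m$FN, m$TN), c(2, 1, 1, 6))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$npv, 6 / 7)
  expect_equal(m$ppv, m$precision)
})

test_that("AUROC handles perfect, random-tie and degenerate cases", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2)), 1.0)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.3)), 0.5)
  expect_error(auroc(c(1, 1), c(0.5, 0.6)), "both classes")
  m <- compute_metrics(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(m$auroc))
  expect_true("auroc_undefined" %in% m$degenerate_flags)
  expect_equal(m$recall, 0.5)  # other metrics still computed
  m0 <- compute_metrics(c(0, 1), c(0.1, 0.2))
  expect_true("precision" %in% m0$degenerate_flags)
  expect_equal(m0$precision, 0)
})

test_that("trapezoidal AUROC equals brute-force pair concordance", {
  brute_auc <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(5:40, 1L)
    labels <- c(0, 1, sample(c(0, 1), n - 2L, TRUE))
    scores <- round(runif(n), sample(c(1, 2, 5), 1L))  # force ties
    expect_equal(auroc(labels, scores), brute_auc(labels, scores),
                 tolerance = 1e-9)
  }
})

test_that("paired t-test matches stats::t.test and handles degeneracy", {
  set.seed(6)
  a <- runif(25)
  b <- a + 0.05 + rnorm(25, sd = 0.01)
  res <- paired_ttest(b, a)
  ref <- t.test(b, a, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_lt(res$p_value, 0.05)
  # swapping negates t and preserves p
  swapped <- paired_ttest(a, b)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  # identical vectors -> t = 0, degenerate flag
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_true(same$degenerate)
  # constant nonzero difference -> signed infinite statistic, p = 0
  shifted <- paired_ttest(a + 0.1, a)
  expect_equal(shifted$t, Inf)
  expect_true(shifted$degenerate)
})

test_that("run_protocol produces n_subsets x n_folds scores per model", {
  insts <- small_cohort_instances(140L, seed = 12L)
  tc <- train_config(epochs = 3L, hidden_width = 4L, seed = 5L)
  ec <- eval_config(n_subsets = 2L, n_folds = 2L, seed = 9L)
  rep1 <- run_protocol(c("logistic", "decision_tree"), insts,
                       train_cfg = tc, eval_cfg = ec)
  expect_equal(nrow(rep1$scores), 2L * 2L * 2L)
  expect_equal(sum(rep1$scores$model == "logistic"), 4L)
  agg <- rep1$aggregate
  f1s <- rep1$scores$f1[rep1$scores$model == "logistic"]
  expect_equal(agg$mean[agg$model == "logistic" & agg$metric == "f1"],
               mean(f1s))
  expect_equal(agg$sd[agg$model == "logistic" & agg$metric == "f1"],
               sd(f1s))
  # fold confusion counts sum to the test-fold size
  expect_true(all(rowSums(rep1$scores[, c("TP", "FP", "FN", "TN")]) >=
                    1))
  # t-tests cover each model pair and metric
  expect_equal(nrow(rep1$ttests), 5L)
  # identical config + seed reproduces the report exactly
  rep2 <- run_protocol(c("logistic", "decision_tree"), insts,
                       train_cfg = tc, eval_cfg = ec)
  expect_identical(rep1$scores, rep2$scores)
})
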