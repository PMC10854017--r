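#' Evaluation configuration
#'
#' The reference protocol balances the classes by undersampling the
#' majority (non-revisit) class into five subsets and runs five-fold
#' cross-validation within each, averaging the resulting 25 fold scores.
#'
#' @param n_subsets Positive integer, number of balanced subsets.
#' @param n_folds Integer >= 2, folds per subset.
#' @param seed Integer seed for subset sampling and fold assignment.
#' @param stratified_folds Logical; stratify folds by label (default).
#' @return An `eval_config` list.
#' @export
eval_config <- function(n_subsets = 5L, n_folds = 5L, seed = 1L,
                        stratified_folds = TRUE) {
  n_subsets <- as.integer(n_subsets)
  n_folds <- as.integer(n_folds)
  stopifnot(n_subsets >= 1L, n_folds >= 2L)
  structure(list(n_subsets = n_subsets, n_folds = n_folds,
                 seed = as.integer(seed),
                 stratified_folds = isTRUE(stratified_folds)),
            class = "eval_config")
}

#' Balanced datasets by undersampling the majority class
#'
#' Each subset contains every positive (revisit) instance plus a uniform
#' random sample, without replacement within the subset and independent
#' across subsets, of the same number of negatives; subset size is
#' twice the positive count. Negatives may recur across subsets.
#'
#' @param instances List of `labeled_instance`.
#' @param cfg An [eval_config()].
#' @return List of `cfg$n_subsets` lists of instances.
#' @export
make_balanced_subsets <- function(instances, cfg = eval_config()) {
  y <- instance_labels(instances)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (length(neg) < length(pos)) {
    stop("fewer negatives (", length(neg), ") than positives (",
         length(pos), "): undersampling direction violated", call. = FALSE)
  }
  lapply(seq_len(cfg$n_subsets), function(s) {
    set.seed(derive_seed(cfg$seed, 11L, s))
    sampled <- if (length(neg) == length(pos)) neg else
      sample(neg, length(pos))
    instances[c(pos, sort(sampled))]
  })
}

#' k-fold cross-validation splits
#'
#' Partitions a dataset into `n_folds` test folds as equal as integer
#' division allows (stratified by label when enabled, keeping each
#' fold's class balance within one instance of the dataset's). Test
#' folds are pairwise disjoint and their union is the dataset.
#'
#' @param dataset List of `labeled_instance` (or any list when
#'   `labels` is given).
#' @param cfg An [eval_config()].
#' @param labels Optional integer labels; default extracted from
#'   `dataset`.
#' @return List of `n_folds` lists with integer index vectors `train`
#'   and `test`.
#' @export
kfold_splits <- function(dataset, cfg = eval_config(), labels = NULL) {
  n <- length(dataset)
  if (n < cfg$n_folds) {
    stop("dataset size ", n, " smaller than n_folds ", cfg$n_folds,
         call. = FALSE)
  }
  if (is.null(labels)) labels <- instance_labels(dataset)
  set.seed(derive_seed(cfg$seed, 12L, n))
  fold_of <- integer(n)
  if (cfg$stratified_folds) {
    # one continuous cyclic assignment across class blocks keeps both
    # the overall fold sizes and each class's split within one instance
    ordered <- unlist(lapply(sort(unique(labels)), function(cls) {
      idx <- which(labels == cls)
      idx[sample.int(length(idx))]
    }))
    fold_of[ordered] <- rep_len(seq_len(cfg$n_folds), n)
  } else {
    fold_of[sample.int(n)] <- rep_len(seq_len(cfg$n_folds), n)
  }
  lapply(seq_len(cfg$n_folds), function(k) {
    list(train = which(fold_of != k), test = which(fold_of == k))
  })
}

#' ROC points over all score thresholds
#'
#' @param labels Binary labels (0/1) with both classes present.
#' @param scores Numeric scores (higher = more positive).
#' @return data.frame with columns `fpr`, `tpr` ordered from (0,0) to
#'   (1,1), one point per distinct threshold (ties grouped).
#' @export
roc_points <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  # group tied scores so each distinct threshold yields one point
  last_of_group <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  P <- sum(y)
  N <- length(y) - P
  if (P == 0L || N == 0L) {
    stop("ROC requires both classes in labels", call. = FALSE)
  }
  data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal integration of the ROC over all thresholds; equal to the
#' concordance probability with ties counted 1/2.
#'
#' @inheritParams roc_points
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  pts <- roc_points(labels, scores)
  sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-nrow(pts)]) / 2)
}

#' Confusion-matrix metrics for one fold
#'
#' Computes the full metric set at a probability threshold: precision
#' (= PPV), recall, F1, accuracy, NPV, and trapezoidal AUROC. A
#' zero-denominator metric is reported as 0 and named in
#' `degenerate_flags`; single-class labels make AUROC undefined (`NA`,
#' flagged) while the threshold metrics are still computed.
#'
#' @param labels Binary labels.
#' @param probabilities Scores in \[0, 1\].
#' @param threshold Label cut-point (predicted 1 iff `>=`).
#' @return A `fold_metrics` list with `TP`, `FP`, `FN`, `TN`, the
#'   metrics, `roc` points (or `NULL`) and `degenerate_flags`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  stopifnot(length(labels) == length(probabilities),
            all(labels %in% c(0L, 1L)),
            all(probabilities >= 0 & probabilities <= 1))
  pred <- as.integer(probabilities >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  FP <- sum(pred == 1L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  TN <- sum(pred == 0L & labels == 0L)
  flags <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      0
    } else num / den
  }
  precision <- safe_div(TP, TP + FP, "precision")
  recall <- safe_div(TP, TP + FN, "recall")
  f1 <- if (precision + recall == 0) {
    flags <- c(flags, "f1")
    0
  } else 2 * precision * recall / (precision + recall)
  npv <- safe_div(TN, TN + FN, "npv")
  auc <- NA_real_
  roc <- NULL
  if (length(unique(labels)) < 2L) {
    flags <- c(flags, "auroc_undefined")
  } else {
    roc <- roc_points(labels, probabilities)
    auc <- sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
  }
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 f1 = f1, precision = precision, recall = recall,
                 accuracy = (TP + TN) / length(labels),
                 auroc = auc, ppv = precision, npv = npv,
                 roc = roc, degenerate_flags = flags),
            class = "fold_metrics")
}

#' Paired two-sided t-test on fold-aligned scores
#'
#' All models are evaluated on identical subset/fold splits, so scores
#' pair naturally by fold; the test is on the fold-wise differences with
#' `length - 1` degrees of freedom. Zero-variance differences are
#' flagged degenerate instead of failing: the statistic is 0 when the
#' mean difference is 0 and signed infinite otherwise.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (length >= 2).
#' @return List with `t`, `p_value`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  n <- length(d)
  sd_d <- stats::sd(d)
  # treat numerically-zero variance (relative to the mean difference)
  # as degenerate
  if (sd_d <= max(1e-14, 1e-9 * abs(mean(d)))) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_stat,
                p_value = if (t_stat == 0) 1 else 0,
                df = n - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, mean_diff = mean(d), degenerate = FALSE)
}

metric_names <- function() {
  c("f1", "precision", "recall", "accuracy", "auroc", "ppv", "npv")
}

#' Run the balanced-undersampling repeated CV protocol
#'
#' For each balanced subset and each fold: fit every requested model on
#' the four training folds (schema fitted on training data only, shared
#' across models) and score it on the held-out fold. All models see
#' identical splits. Scores are aggregated as mean and SD over the
#' `n_subsets x n_folds` folds, and models are compared pairwise with
#' paired t-tests on F1, precision, recall, AUROC and accuracy.
#'
#' @param kinds Character vector of [model_kinds()] to run.
#' @param instances List of `labeled_instance` with both classes.
#' @param train_cfg A [train_config()].
#' @param eval_cfg An [eval_config()].
#' @param preprocess A [preprocess_config()].
#' @param fpr_grid Grid of false-positive rates at which per-fold ROC
#'   curves are vertically averaged for reporting.
#' @param verbose Print per-fold progress lines.
#' @return An `evaluation_report`: list with `scores` (data.frame:
#'   model, subset, fold, confusion counts and metrics), `aggregate`
#'   (mean and sd per model x metric), `ttests` (pairwise, per metric),
#'   `roc` (averaged TPR per model at `fpr_grid`), and the configs.
#' @export
run_protocol <- function(kinds, instances,
                         train_cfg = train_config(),
                         eval_cfg = eval_config(),
                         preprocess = preprocess_config(),
                         fpr_grid = seq(0, 1, by = 0.02),
                         verbose = FALSE) {
  kinds <- vapply(kinds, match.arg, "", choices = model_kinds())
  subsets <- make_balanced_subsets(instances, eval_cfg)
  rows <- list()
  roc_acc <- lapply(kinds, function(k) NULL)
  names(roc_acc) <- kinds
  for (s in seq_along(subsets)) {
    ds <- subsets[[s]]
    sub_cfg <- eval_config(eval_cfg$n_subsets, eval_cfg$n_folds,
                           seed = derive_seed(eval_cfg$seed, 13L, s),
                           stratified_folds = eval_cfg$stratified_folds)
    splits <- kfold_splits(ds, sub_cfg)
    for (k in seq_along(splits)) {
      train_set <- ds[splits[[k]]$train]
      test_set <- ds[splits[[k]]$test]
      test_y <- instance_labels(test_set)
      schema <- fit_schema(train_set, preprocess)
      fold_cfg <- train_cfg
      fold_cfg$seed <- derive_seed(train_cfg$seed, s, k)
      for (kind in kinds) {
        fit <- train_model(kind, train_set, fold_cfg, schema = schema,
                           preprocess = preprocess)
        pr <- predict(fit, test_set)
        m <- compute_metrics(test_y, pr$probabilities,
                             fold_cfg$threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          model = kind, subset = s, fold = k,
          TP = m$TP, FP = m$FP, FN = m$FN, TN = m$TN,
          f1 = m$f1, precision = m$precision, recall = m$recall,
          accuracy = m$accuracy, auroc = m$auroc, ppv = m$ppv,
          npv = m$npv, stringsAsFactors = FALSE)
        if (!is.null(m$roc)) {
          tpr_at <- stats::approx(m$roc$fpr, m$roc$tpr, xout = fpr_grid,
                                  ties = max, rule = 2)$y
          roc_acc[[kind]] <- rbind(roc_acc[[kind]], tpr_at)
        }
        if (verbose) {
          message(sprintf("subset %d fold %d %s: F1=%.4f AUROC=%.4f",
                          s, k, kind, m$f1, m$auroc))
        }
      }
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  aggregate <- do.call(rbind, lapply(kinds, function(kind) {
    sub <- scores[scores$model == kind, metric_names(), drop = FALSE]
    data.frame(model = kind, metric = metric_names(),
               mean = vapply(sub, mean, 1, na.rm = TRUE),
               sd = vapply(sub, stats::sd, 1, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(aggregate) <- NULL
  ttests <- NULL
  if (length(kinds) > 1L) {
    cmp_metrics <- c("f1", "precision", "recall", "auroc", "accuracy")
    pairs <- utils::combn(kinds, 2L, simplify = FALSE)
    ttests <- do.call(rbind, lapply(pairs, function(pr2) {
      do.call(rbind, lapply(cmp_metrics, function(mt) {
        a <- scores[scores$model == pr2[1L], mt]
        b <- scores[scores$model == pr2[2L], mt]
        tt <- paired_ttest(a, b)
        data.frame(model_a = pr2[1L], model_b = pr2[2L], metric = mt,
                   t = tt$t, p_value = tt$p_value, df = tt$df,
                   mean_diff = tt$mean_diff, degenerate = tt$degenerate,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(ttests) <- NULL
  }
  roc_mean <- lapply(roc_acc, function(mat) {
    if (is.null(mat)) return(NULL)
    data.frame(fpr = fpr_grid, tpr = colMeans(mat))
  })
  structure(list(scores = scores, aggregate = aggregate, ttests = ttests,
                 roc = roc_mean, kinds = kinds,
                 train_cfg = train_cfg, eval_cfg = eval_cfg,
                 preprocess = preprocess),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", length(x$kinds), "model(s),",
      nrow(x$scores) / length(x$kinds), "fold scores each\n\n")
  agg <- x$aggregate
  for (kind in x$kinds) {
    sub <- agg[agg$model == kind, ]
    cat(sprintf("%-18s F1 %.4f (%.4f)  AUROC %.4f  acc %.4f\n", kind,
                sub$mean[sub$metric == "f1"], sub$sd[sub$metric == "f1"],
                sub$mean[sub$metric == "auroc"],
                sub$mean[sub$metric == "accuracy"]))
  }
  invisible(x)
}
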