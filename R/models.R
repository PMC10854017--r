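#' Training configuration
#'
#' Shared settings for the neural models and baselines. The reference
#' protocol trains the GNN and RNN for 300 epochs in minibatches of 500
#' on binary cross-entropy; hidden width and learning rate are not fixed
#' by the protocol and default to values tuned once on synthetic data.
#'
#' @param epochs Positive integer, training epochs for gnn/rnn.
#' @param batch_size Positive integer, minibatch size.
#' @param learning_rate Positive Adam step size.
#' @param hidden_width Positive integer, hidden layer width.
#' @param seed Integer seed controlling initialization and batching.
#' @param threshold Probability cut-point for label metrics (a predicted
#'   probability `>= threshold` is labelled 1).
#' @param gnn_aggregation Neighbour aggregation: `"mean"`
#'   (degree-normalized with self-inclusion, default) or `"sum"`.
#' @param gnn_readout Graph readout: `"all"` nodes (default) or
#'   `"visits"` nodes only.
#' @param rnn_cell Recurrent cell: `"gru"` (default) or `"tanh"`.
#' @param tree_max_depth,boost_rounds,boost_depth,boost_eta,boost_lambda,logistic_lambda
#'   Baseline hyperparameters: decision-tree depth cap; boosting rounds,
#'   tree depth, shrinkage and L2 penalty; ridge penalty of the logistic
#'   model.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 500L,
                         learning_rate = 1e-2, hidden_width = 64L,
                         seed = 1L, threshold = 0.5,
                         gnn_aggregation = c("mean", "sum"),
                         gnn_readout = c("all", "visits"),
                         rnn_cell = c("gru", "tanh"),
                         tree_max_depth = 25L,
                         boost_rounds = 50L, boost_depth = 3L,
                         boost_eta = 0.3, boost_lambda = 1,
                         logistic_lambda = 1e-3) {
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            hidden_width >= 1L, threshold > 0, threshold < 1)
  structure(list(
    epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, hidden_width = as.integer(hidden_width),
    seed = as.integer(seed), threshold = threshold,
    gnn_aggregation = match.arg(gnn_aggregation),
    gnn_readout = match.arg(gnn_readout),
    rnn_cell = match.arg(rnn_cell),
    tree_max_depth = as.integer(tree_max_depth),
    boost_rounds = as.integer(boost_rounds),
    boost_depth = as.integer(boost_depth),
    boost_eta = boost_eta, boost_lambda = boost_lambda,
    logistic_lambda = logistic_lambda
  ), class = "train_config")
}

#' Model kinds available for training
#' @return Character vector of the five supported model kinds.
#' @export
model_kinds <- function() {
  c("gnn", "rnn", "logistic", "decision_tree", "gradient_boosting")
}

#' Flatten an instance into a fixed-width baseline row
#'
#' Concatenates the encoded visits into a single row of
#' `visit_cap * schema$width` slots, right-aligned in temporal order:
#' the most recent visit occupies the last slot and earlier slots are
#' zero-padded on the left, so temporal position is preserved across
#' patients with different visit counts.
#'
#' @param instance A `labeled_instance`.
#' @param schema A fitted [fit_schema()] result.
#' @param visit_cap Number of visit slots (the preprocessing cap).
#' @return Numeric vector of length `visit_cap * schema$width`.
#' @export
flatten_for_baseline <- function(instance, schema, visit_cap = 10L) {
  enc <- encode_instance_matrix(instance, schema)
  n <- nrow(enc)
  stopifnot(n <= visit_cap)
  out <- numeric(visit_cap * schema$width)
  start <- (visit_cap - n) * schema$width
  out[(start + 1L):(start + n * schema$width)] <- as.numeric(t(enc))
  out
}

baseline_matrix <- function(instances, schema, visit_cap) {
  t(vapply(instances, flatten_for_baseline, numeric(visit_cap * schema$width),
           schema = schema, visit_cap = visit_cap))
}

#' Train a revisit classifier
#'
#' Fits one of the five model kinds on labelled instances: `"gnn"` (the
#' one-layer graph classifier on per-patient graphs), `"rnn"` (the gated
#' sequence classifier on encoded visit sequences), or the baselines
#' `"logistic"` (L2), `"decision_tree"` (CART) and
#' `"gradient_boosting"` (second-order boosting), which see the visits
#' concatenated into a single fixed-width row. The feature schema is
#' fitted on `instances` unless one is supplied, so cross-validation can
#' fit it on training folds only.
#'
#' @param model_kind One of [model_kinds()].
#' @param instances Non-empty list of `labeled_instance` with both
#'   classes present.
#' @param cfg A [train_config()].
#' @param schema Optional pre-fitted [fit_schema()]; default fits on
#'   `instances`.
#' @param preprocess A [preprocess_config()] (for the visit cap and age
#'   normalization used when fitting the schema).
#' @return An `ed_predictor` with elements `kind`, `params`, `schema`,
#'   `cfg`.
#' @export
train_model <- function(model_kind, instances, cfg = train_config(),
                        schema = NULL,
                        preprocess = preprocess_config()) {
  model_kind <- match.arg(model_kind, model_kinds())
  if (length(instances) == 0L) stop("no training instances", call. = FALSE)
  y <- instance_labels(instances)
  if (all(y == 1L)) stop("single-class training set: class 0 missing",
                         call. = FALSE)
  if (all(y == 0L)) stop("single-class training set: class 1 missing",
                         call. = FALSE)
  if (is.null(schema)) schema <- fit_schema(instances, preprocess)
  params <- switch(
    model_kind,
    gnn = {
      graphs <- lapply(instances, build_patient_graph, schema = schema)
      fit_gnn(graphs, y, cfg)
    },
    rnn = {
      seqs <- lapply(instances, encode_instance_matrix, schema = schema)
      fit_rnn(seqs, y, cfg)
    },
    logistic = {
      X <- baseline_matrix(instances, schema, preprocess$visit_cap)
      fit <- glmnet::glmnet(X, factor(y, levels = c(0L, 1L)),
                            family = "binomial", alpha = 0,
                            lambda = cfg$logistic_lambda,
                            standardize = FALSE)
      list(fit = fit, visit_cap = preprocess$visit_cap)
    },
    decision_tree = {
      X <- baseline_matrix(instances, schema, preprocess$visit_cap)
      list(fit = fit_cart(X, y, max_depth = cfg$tree_max_depth),
           visit_cap = preprocess$visit_cap)
    },
    gradient_boosting = {
      X <- baseline_matrix(instances, schema, preprocess$visit_cap)
      list(fit = fit_gbm(X, y, n_rounds = cfg$boost_rounds,
                         max_depth = cfg$boost_depth, eta = cfg$boost_eta,
                         lambda = cfg$boost_lambda),
           visit_cap = preprocess$visit_cap)
    }
  )
  structure(list(kind = model_kind, params = params, schema = schema,
                 cfg = cfg, visit_cap = preprocess$visit_cap),
            class = "ed_predictor")
}

#' @export
print.ed_predictor <- function(x, ...) {
  cat("ed_predictor:", x$kind, "| feature width", x$schema$width, "\n")
  invisible(x)
}

#' Predict revisit probabilities and thresholded labels
#'
#' @param object A fitted `ed_predictor`.
#' @param instances List of `labeled_instance` encodable under the
#'   predictor's schema (codes unseen at fit time map to zero blocks).
#' @param ... Unused.
#' @return List with `probabilities` (in \[0,1\]) and `labels`
#'   (1 iff probability `>= threshold`).
#' @export
predict.ed_predictor <- function(object, instances, ...) {
  if (is.null(object$params)) stop("unfitted predictor", call. = FALSE)
  if (inherits(instances, "labeled_instance")) instances <- list(instances)
  p <- switch(
    object$kind,
    gnn = {
      graphs <- lapply(instances, build_patient_graph,
                       schema = object$schema)
      gnn_forward(batch_graphs(graphs), object$params)
    },
    rnn = {
      seqs <- lapply(instances, encode_instance_matrix,
                     schema = object$schema)
      rnn_forward(seqs, object$params)
    },
    logistic = {
      X <- baseline_matrix(instances, object$schema, object$visit_cap)
      as.numeric(stats::predict(object$params$fit, X, type = "response"))
    },
    decision_tree = {
      X <- baseline_matrix(instances, object$schema, object$visit_cap)
      predict_cart(object$params$fit, X)
    },
    gradient_boosting = {
      X <- baseline_matrix(instances, object$schema, object$visit_cap)
      predict_gbm(object$params$fit, X)
    }
  )
  list(probabilities = p,
       labels = as.integer(p >= object$cfg$threshold))
}
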