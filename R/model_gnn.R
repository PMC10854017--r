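# One-layer graph convolutional classifier over patient graphs.
#
# Forward pass per batch:
#   Ahat = D^-1 (A + I)      (degree-normalized neighbour mean with
#                             self-inclusion; "sum" skips normalization)
#   H    = relu(Ahat X W1 + b1)      one message-passing layer
#   Z    = P H                       per-graph mean-pool readout
#   p    = sigmoid(Z w2 + b2)        graph-level probability
#
# Because the graph and input features are fixed during training, the
# propagated input M = Ahat X is precomputed once per graph, reducing
# each training step to dense matrix products.

normalize_adjacency <- function(adjacency, aggregation = "mean") {
  A <- adjacency + Matrix::Diagonal(nrow(adjacency))
  if (aggregation == "mean") {
    d <- Matrix::rowSums(A)
    A <- A / d  # row-scale
  }
  A
}

gnn_init_params <- function(feature_width, hidden_width, seed,
                            aggregation = "mean", readout = "all") {
  set.seed(seed)
  list(W1 = glorot(feature_width, hidden_width),
       b1 = numeric(hidden_width),
       w2 = glorot(hidden_width, 1L)[, 1L],
       b2 = 0,
       aggregation = aggregation,
       readout = readout)
}

batch_pool <- function(batch, readout) {
  if (identical(readout, "visits")) batch$pool_visits else batch$pool
}

#' Forward pass of the one-layer GNN graph classifier
#'
#' One degree-normalized message-passing layer with self-inclusion, a
#' ReLU nonlinearity, mean-pool readout over the graph's nodes and a
#' sigmoid output unit. With all-zero weights every graph scores 0.5.
#' The output is invariant to node relabelling within a graph and to
#' graph order within a batch.
#'
#' @param batch A [batch_graphs()] result.
#' @param params Parameter list with `W1` (width x hidden), `b1`, `w2`
#'   (hidden), `b2`, and options `aggregation` (`"mean"` or `"sum"`) and
#'   `readout` (`"all"` or `"visits"`), e.g. from a fitted predictor's
#'   `$params`.
#' @return Numeric vector of per-graph probabilities.
#' @export
gnn_forward <- function(batch, params) {
  stopifnot(inherits(batch, "graph_batch"))
  if (ncol(params$W1) != length(params$w2) ||
      nrow(params$W1) != ncol(batch$features)) {
    stop("parameter dimensions do not match batch feature width",
         call. = FALSE)
  }
  Ahat <- normalize_adjacency(batch$adjacency,
                              params$aggregation %||% "mean")
  M <- as.matrix(Ahat %*% batch$features)
  H <- relu(sweep(M %*% params$W1, 2L, params$b1, "+"))
  Z <- as.matrix(batch_pool(batch, params$readout %||% "all") %*% H)
  as.numeric(sigmoid(Z %*% params$w2 + params$b2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Precompute per-graph propagated inputs M_g = Ahat_g X_g and stack them.
gnn_precompute <- function(graphs, aggregation) {
  Ms <- lapply(graphs, function(g) {
    A <- g$adjacency + diag(nrow(g$adjacency))
    if (aggregation == "mean") A <- A / rowSums(A)
    A %*% g$features
  })
  sizes <- vapply(Ms, nrow, 1L)
  list(M = do.call(rbind, Ms), sizes = sizes,
       offsets = cumsum(c(0L, sizes[-length(sizes)])),
       n_visits = vapply(graphs, function(g) g$n_visits, 1L))
}

# Node rows and pooling weights for a subset of graphs, given the
# precomputed node blocks. Pooling is done with base rowsum()/indexing
# (no sparse products) to keep the training loop cheap.
subset_pool <- function(pre, idx, readout) {
  if (identical(readout, "visits")) {
    counts <- pre$n_visits[idx]
    rows <- unlist(lapply(seq_along(idx), function(k)
      pre$offsets[idx[k]] + seq_len(counts[k])))
  } else {
    counts <- pre$sizes[idx]
    rows <- unlist(lapply(idx, function(g)
      pre$offsets[g] + seq_len(pre$sizes[g])))
  }
  list(rows = rows,
       gidx = rep(seq_along(idx), counts),
       wts = 1 / rep(counts, counts))
}

# Analytic gradient of mean BCE wrt all parameters for one minibatch.
# b$gidx maps node rows to graphs (ascending), b$wts are the per-node
# mean-pool weights.
gnn_grad <- function(b, params) {
  Pre <- b$M %*% params$W1
  Pre <- Pre + rep(params$b1, each = nrow(Pre))
  pos <- Pre > 0
  H <- Pre * pos
  Z <- rowsum(H * b$wts, b$gidx)
  p <- as.numeric(sigmoid(Z %*% params$w2 + params$b2))
  y <- b$y
  dlog <- (p - y) / length(y)
  dZ <- outer(dlog, params$w2)
  dPre <- (dZ[b$gidx, , drop = FALSE] * b$wts) * pos
  list(loss = bce_loss(p, y),
       grads = list(W1 = crossprod(b$M, dPre),
                    b1 = colSums(dPre),
                    w2 = as.numeric(crossprod(Z, dlog)),
                    b2 = sum(dlog)))
}

fit_gnn <- function(graphs, labels, cfg) {
  pre <- gnn_precompute(graphs, cfg$gnn_aggregation)
  params <- gnn_init_params(ncol(pre$M), cfg$hidden_width,
                            derive_seed(cfg$seed, 101L),
                            cfg$gnn_aggregation, cfg$gnn_readout)
  opt_par <- params[c("W1", "b1", "w2", "b2")]
  state <- adam_init(opt_par)
  batches <- make_batches(length(graphs), cfg$batch_size,
                          derive_seed(cfg$seed, 102L))
  prepared <- lapply(batches, function(idx) {
    sp <- subset_pool(pre, idx, cfg$gnn_readout)
    list(M = pre$M[sp$rows, , drop = FALSE], gidx = sp$gidx,
         wts = sp$wts, y = labels[idx])
  })
  loss_trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ep_loss <- 0
    for (b in prepared) {
      g <- gnn_grad(b, opt_par)
      upd <- adam_step(opt_par, g$grads, state, cfg$learning_rate)
      opt_par <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + g$loss * length(b$y)
    }
    loss_trace[ep] <- ep_loss / length(graphs)
  }
  c(opt_par,
    list(aggregation = cfg$gnn_aggregation, readout = cfg$gnn_readout,
         loss_trace = loss_trace))
}
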