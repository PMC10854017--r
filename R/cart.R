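# Decision tree (CART, Gini) and second-order gradient boosting on
# logistic loss, both on the flattened fixed-width visit rows. The
# feature matrix is almost entirely 0/1 (one-/multi-hot blocks), which
# the split search exploits: all binary columns are scored with two
# matrix products per node; the few numeric columns (the age slots) get
# a sorted scan.
#
# Split convention: rows go left when x <= threshold (0.5 for binary
# columns). Ties in gain break to the lowest column index, then lowest
# threshold, so fits are deterministic.

detect_binary_cols <- function(X) {
  apply(X, 2L, function(col) all(col == 0 | col == 1))
}

# Best split under the xgboost-style second-order gain; g, h are the
# per-row gradient/hessian of the logistic loss at the current score.
xgb_split <- function(X, is_bin, g, h, rows, lambda, min_leaf) {
  Xs <- X[rows, , drop = FALSE]
  gs <- g[rows]; hs <- h[rows]
  G <- sum(gs); H <- sum(hs)
  parent <- G * G / (H + lambda)
  best <- list(gain = 0, col = NA_integer_, thr = NA_real_)
  nb <- which(is_bin)
  if (length(nb) > 0L) {
    Xb <- Xs[, nb, drop = FALSE]
    left <- 1 - Xb  # indicator x <= 0.5
    GL <- as.numeric(crossprod(left, gs))
    HL <- as.numeric(crossprod(left, hs))
    nL <- as.numeric(colSums(left))
    GR <- G - GL; HR <- H - HL
    nR <- length(rows) - nL
    gain <- GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent
    gain[nL < min_leaf | nR < min_leaf] <- -Inf
    k <- which.max(gain)
    if (length(k) == 1L && gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], col = nb[k], thr = 0.5)
    }
  }
  for (j in which(!is_bin)) {
    x <- Xs[, j]
    ord <- order(x, method = "radix")
    xo <- x[ord]
    cg <- cumsum(gs[ord]); ch <- cumsum(hs[ord])
    n <- length(xo)
    cut <- which(xo[-n] < xo[-1L])  # split between distinct values
    if (length(cut) == 0L) next
    cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
    if (length(cut) == 0L) next
    GL <- cg[cut]; HL <- ch[cut]
    gain <- GL^2 / (HL + lambda) + (G - GL)^2 / (H - HL + lambda) - parent
    k <- which.max(gain)
    if (gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], col = j,
                   thr = (xo[cut[k]] + xo[cut[k] + 1L]) / 2)
    }
  }
  best
}

# Best split by Gini impurity decrease for the classification tree.
gini_split <- function(X, is_bin, y, rows, min_leaf) {
  Xs <- X[rows, , drop = FALSE]
  ys <- y[rows]
  n <- length(rows)
  n1 <- sum(ys)
  gini <- function(nl1, nl) {
    # total weighted impurity of a left/right partition
    nr <- n - nl; nr1 <- n1 - nl1
    il <- ifelse(nl > 0, 1 - (nl1 / nl)^2 - ((nl - nl1) / nl)^2, 0)
    ir <- ifelse(nr > 0, 1 - (nr1 / nr)^2 - ((nr - nr1) / nr)^2, 0)
    (nl * il + nr * ir) / n
  }
  parent <- 1 - (n1 / n)^2 - ((n - n1) / n)^2
  best <- list(gain = 0, col = NA_integer_, thr = NA_real_)
  nb <- which(is_bin)
  if (length(nb) > 0L) {
    left <- 1 - Xs[, nb, drop = FALSE]
    nL1 <- as.numeric(crossprod(left, ys))
    nL <- as.numeric(colSums(left))
    gain <- parent - gini(nL1, nL)
    gain[nL < min_leaf | (n - nL) < min_leaf] <- -Inf
    k <- which.max(gain)
    if (length(k) == 1L && gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], col = nb[k], thr = 0.5)
    }
  }
  for (j in which(!is_bin)) {
    x <- Xs[, j]
    ord <- order(x, method = "radix")
    xo <- x[ord]
    c1 <- cumsum(ys[ord])
    cut <- which(xo[-n] < xo[-1L])
    cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
    if (length(cut) == 0L) next
    gain <- parent - gini(c1[cut], cut)
    k <- which.max(gain)
    if (gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], col = j,
                   thr = (xo[cut[k]] + xo[cut[k] + 1L]) / 2)
    }
  }
  best
}

# Grow a tree; `leaf_value(rows)` and `find_split(rows, depth)` are
# closures, so the same grower serves CART and boosting.
grow_tree <- function(n_rows_total, find_split, leaf_value, max_depth,
                      min_split) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  build <- function(rows, depth) {
    id <- new_node()
    nodes[[id]] <<- list(leaf = TRUE, pred = leaf_value(rows),
                         col = NA_integer_, thr = NA_real_,
                         left = NA_integer_, right = NA_integer_)
    if (depth >= max_depth || length(rows) < min_split) return(id)
    sp <- find_split(rows, depth)
    if (is.na(sp$col)) return(id)
    nodes[[id]]$leaf <<- FALSE
    nodes[[id]]$col <<- sp$col
    nodes[[id]]$thr <<- sp$thr
    go_left <- sp$rows_left
    nodes[[id]]$left <<- build(rows[go_left], depth + 1L)
    nodes[[id]]$right <<- build(rows[!go_left], depth + 1L)
    id
  }
  root <- build(seq_len(n_rows_total), 0L)
  list(nodes = nodes, root = root)
}

tree_apply <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  node_of <- rep(tree$root, n)
  repeat {
    leafs <- vapply(tree$nodes[node_of], function(nd) nd$leaf, TRUE)
    if (all(leafs)) break
    act <- which(!leafs)
    for (id in unique(node_of[act])) {
      nd <- tree$nodes[[id]]
      if (nd$leaf) next
      rows <- act[node_of[act] == id]
      left <- X[rows, nd$col] <= nd$thr
      node_of[rows[left]] <- nd$left
      node_of[rows[!left]] <- nd$right
    }
  }
  for (id in unique(node_of)) {
    out[node_of == id] <- tree$nodes[[id]]$pred
  }
  out
}

# CART classification tree; leaf prediction is the positive fraction.
fit_cart <- function(X, y, max_depth = 25L, min_split = 2L,
                     min_leaf = 1L) {
  stopifnot(nrow(X) == length(y))
  is_bin <- detect_binary_cols(X)
  find_split <- function(rows, depth) {
    ys <- y[rows]
    if (all(ys == ys[1L])) return(list(col = NA_integer_))
    sp <- gini_split(X, is_bin, y, rows, min_leaf)
    if (is.na(sp$col)) return(sp)
    sp$rows_left <- X[rows, sp$col] <= sp$thr
    sp
  }
  tree <- grow_tree(nrow(X), find_split, function(rows) mean(y[rows]),
                    max_depth, min_split)
  structure(list(tree = tree), class = "cart_tree")
}

predict_cart <- function(model, X) {
  tree_apply(model$tree, X)
}

# Gradient boosting with second-order (Newton) leaf weights on logistic
# loss: per round fit a depth-limited tree to (g, h), leaf weight
# -G/(H+lambda), shrunk by eta.
fit_gbm <- function(X, y, n_rounds = 50L, max_depth = 3L, eta = 0.3,
                    lambda = 1, min_leaf = 1L) {
  stopifnot(nrow(X) == length(y))
  is_bin <- detect_binary_cols(X)
  p0 <- mean(y)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  base <- log(p0 / (1 - p0))
  Fx <- rep(base, length(y))
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    p <- sigmoid(Fx)
    g <- p - y
    h <- p * (1 - p)
    find_split <- function(rows, depth) {
      sp <- xgb_split(X, is_bin, g, h, rows, lambda, min_leaf)
      if (is.na(sp$col)) return(sp)
      sp$rows_left <- X[rows, sp$col] <= sp$thr
      sp
    }
    leaf_value <- function(rows) -sum(g[rows]) / (sum(h[rows]) + lambda)
    tr <- grow_tree(nrow(X), find_split, leaf_value, max_depth,
                    min_split = 2L)
    trees[[m]] <- tr
    Fx <- Fx + eta * tree_apply(tr, X)
  }
  structure(list(trees = trees, base = base, eta = eta),
            class = "gbm_model")
}

predict_gbm <- function(model, X) {
  Fx <- rep(model$base, nrow(X))
  for (tr in model$trees) Fx <- Fx + model$eta * tree_apply(tr, X)
  sigmoid(Fx)
}
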