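test_that("zero-weight networks output probability 0.5", {
  inst <- two_visit_instance()
  sc <- fit_schema(list(inst))
  batch <- batch_graphs(list(build_patient_graph(inst, sc)))
  wf <- ncol(batch$features)
  params <- list(W1 = matrix(0, wf, 4), b1 = numeric(4),
                 w2 = numeric(4), b2 = 0,
                 aggregation = "mean", readout = "all")
  expect_equal(gnn_forward(batch, params), 0.5)
  seqs <- edrevisit:::encode_instance_matrix(inst, sc)
  d <- ncol(seqs)
  zero <- function(n, m) matrix(0, n, m)
  rp <- list(Wz = zero(d, 4), Uz = zero(4, 4), bz = numeric(4),
             Wr = zero(d, 4), Ur = zero(4, 4), br = numeric(4),
             Wh = zero(d, 4), Uh = zero(4, 4), bh = numeric(4),
             w_out = numeric(4), b_out = 0, cell = "gru")
  expect_equal(rnn_forward(seqs, rp), 0.5)
})

test_that("GNN output is invariant to node permutation within a graph", {
  set.seed(3)
  insts <- small_cohort_instances(20L)
  sc <- fit_schema(insts)
  g <- build_patient_graph(insts[[2]], sc)
  nV <- length(g$node_types)
  params <- edrevisit:::gnn_init_params(ncol(g$features), 8L, 42L)
  p_ref <- gnn_forward(batch_graphs(list(g)), params)
  for (rep in 1:5) {
    perm <- sample.int(nV)
    g2 <- g
    g2$adjacency <- g$adjacency[perm, perm]
    g2$features <- g$features[perm, , drop = FALSE]
    p_perm <- gnn_forward(batch_graphs(list(g2)), params)
    expect_equal(p_perm, p_ref, tolerance = 1e-12)
  }
  # and to graph order within a batch
  graphs <- lapply(insts[1:6], build_patient_graph, schema = sc)
  p1 <- gnn_forward(batch_graphs(graphs), params)
  ord <- c(4, 2, 6, 1, 3, 5)
  p2 <- gnn_forward(batch_graphs(graphs[ord]), params)
  expect_equal(p2, p1[ord], tolerance = 1e-12)
})

test_that("single isolated node readout equals its transformed features", {
  x <- matrix(c(1, 0.5, -2), 1, 3)
  g <- structure(list(node_types = "visit", node_names = "visit_1",
                      features = x, edges = data.frame(),
                      adjacency = matrix(0L, 1, 1), label = 0L,
                      n_visits = 1L, services = character(0),
                      diagnoses = character(0)),
                 class = "patient_graph")
  params <- edrevisit:::gnn_init_params(3L, 4L, 7L)
  p <- gnn_forward(batch_graphs(list(g)), params)
  h <- pmax(x %*% params$W1 + rep(params$b1, each = 1), 0)
  expect_equal(p, as.numeric(edrevisit:::sigmoid(h %*% params$w2 +
                                                   params$b2)))
})

test_that("RNN output is order-sensitive; GNN forward matches direct math", {
  set.seed(17)
  d <- 5L
  s <- matrix(rnorm(3 * d), 3, d)
  params <- edrevisit:::rnn_init_params(d, 6L, 11L)
  p_fwd <- rnn_forward(s, params)
  p_rev <- rnn_forward(s[3:1, , drop = FALSE], params)
  expect_false(isTRUE(all.equal(p_fwd, p_rev)))
  # length-1 sequence equals a single recurrent step by hand
  x1 <- s[1, , drop = FALSE]
  st <- edrevisit:::rnn_step_gru(x1, matrix(0, 1, 6), params)
  expect_equal(rnn_forward(x1, params),
               as.numeric(edrevisit:::sigmoid(st$h %*% params$w_out +
                                                params$b_out)))
  expect_error(rnn_forward(matrix(0, 0, d), params), "empty sequence")
})

test_that("analytic GNN gradients match finite differences", {
  set.seed(23)
  insts <- small_cohort_instances(12L)
  sc <- fit_schema(insts)
  graphs <- lapply(insts[1:6], build_patient_graph, schema = sc)
  y <- instance_labels(insts[1:6])
  pre <- edrevisit:::gnn_precompute(graphs, "mean")
  sp <- edrevisit:::subset_pool(pre, 1:6, "all")
  b <- list(M = pre$M[sp$rows, , drop = FALSE], gidx = sp$gidx,
            wts = sp$wts, y = y)
  params <- edrevisit:::gnn_init_params(ncol(b$M), 3L, 5L)
  opt <- params[c("W1", "b1", "w2", "b2")]
  g <- edrevisit:::gnn_grad(b, opt)
  eps <- 1e-6
  for (nm in names(opt)) {
    idx <- sample(seq_along(opt[[nm]]), min(4, length(opt[[nm]])))
    for (i in idx) {
      up <- opt; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- opt; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (edrevisit:::gnn_grad(b, up)$loss -
                edrevisit:::gnn_grad(b, dn)$loss) / (2 * eps)
      expect_equal(as.numeric(g$grads[[nm]][i]), num, tolerance = 1e-5)
    }
  }
})

test_that("analytic RNN gradients match finite differences (gru and tanh)", {
  set.seed(29)
  d <- 4L
  seqs <- lapply(c(1L, 3L, 2L), function(L) matrix(rnorm(L * d), L, d))
  y <- c(1, 0, 1)
  for (cell in c("gru", "tanh")) {
    params <- edrevisit:::rnn_init_params(d, 3L, 31L, cell)
    pad <- edrevisit:::pad_sequences(seqs, d)
    g <- edrevisit:::rnn_grad(pad, y, params)
    opt_names <- setdiff(names(params), "cell")
    eps <- 1e-6
    for (nm in opt_names) {
      idx <- sample(seq_along(params[[nm]]), min(3, length(params[[nm]])))
      for (i in idx) {
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        num <- (edrevisit:::rnn_grad(pad, y, up)$loss -
                  edrevisit:::rnn_grad(pad, y, dn)$loss) / (2 * eps)
        expect_equal(as.numeric(g$grads[[nm]][i]), num,
                     tolerance = 1e-5, label = paste(cell, nm))
      }
    }
  }
})

test_that("flatten_for_baseline right-aligns visits", {
  insts <- separable_instances(1L)
  sc <- fit_schema(insts)
  w <- sc$width
  inst1 <- build_instance(make_history(0L))
  row1 <- flatten_for_baseline(inst1, sc, visit_cap = 10L)
  expect_length(row1, 10L * w)
  expect_true(all(row1[seq_len(9L * w)] == 0))
  expect_gt(sum(row1[9L * w + seq_len(w)] != 0), 0)
  # 3 visits in slots 8..10, in visit order
  inst3 <- build_instance(make_history(c(0L, 40L, 80L, 160L),
                                       diagnosis = c("A", "B", "C", "C")))
  sc3 <- fit_schema(list(inst3))
  row3 <- flatten_for_baseline(inst3, sc3, visit_cap = 10L)
  slots <- matrix(row3, nrow = 10L, byrow = TRUE)
  expect_true(all(rowSums(slots[1:7, , drop = FALSE] != 0) == 0))
  enc <- edrevisit:::encode_instance_matrix(inst3, sc3)
  expect_equal(slots[8, ], enc[1, ])
  expect_equal(slots[10, ], enc[3, ])
  # full cap: no padding
  inst10 <- build_instance(make_history(seq(0L, 400L, by = 40L)))
  sc10 <- fit_schema(list(inst10))
  expect_equal(matrix(flatten_for_baseline(inst10, sc10, 10L),
                      nrow = 10L, byrow = TRUE),
               edrevisit:::encode_instance_matrix(inst10, sc10))
})

test_that("training decreases loss on a separable toy set", {
  insts <- separable_instances(10L)
  cfg <- train_config(epochs = 10L, batch_size = 20L, hidden_width = 8L,
                      seed = 2L)
  for (kind in c("gnn", "rnn")) {
    fit <- train_model(kind, insts, cfg)
    trace <- fit$params$loss_trace
    expect_true(all(diff(trace) < 1e-8),
                label = paste(kind, "monotone loss decrease"))
  }
})

test_that("logistic on a perfectly predictive column reaches high accuracy", {
  insts <- separable_instances(10L)
  fit <- train_model("logistic", insts, train_config(seed = 1L))
  pr <- predict(fit, insts)
  expect_gte(mean(pr$labels == instance_labels(insts)), 0.95)
})

test_that("training errors name the missing class", {
  insts <- separable_instances(4L)
  pos_only <- insts[instance_labels(insts) == 1L]
  expect_error(train_model("logistic", pos_only, train_config()),
               "class 0 missing")
  neg_only <- insts[instance_labels(insts) == 0L]
  expect_error(train_model("gnn", neg_only, train_config()),
               "class 1 missing")
  expect_error(train_model("rnn", list(), train_config()),
               "no training instances")
})

test_that("same seed reproduces fits; prediction is threshold-monotone", {
  insts <- small_cohort_instances(60L, seed = 8L)
  cfg <- train_config(epochs = 5L, hidden_width = 8L, seed = 77L)
  f1 <- train_model("gnn", insts, cfg)
  f2 <- train_model("gnn", insts, cfg)
  p1 <- predict(f1, insts[1:10])
  p2 <- predict(f2, insts[1:10])
  expect_identical(p1$probabilities, p2$probabilities)
  expect_true(all(p1$probabilities >= 0 & p1$probabilities <= 1))
  # label = 1 iff probability >= threshold; raising the threshold never
  # increases the positive count
  pos_counts <- vapply(c(0.2, 0.5, 0.8), function(th) {
    cfg_t <- cfg; cfg_t$threshold <- th
    f <- f1; f$cfg <- cfg_t
    sum(predict(f, insts)$labels)
  }, 1)
  expect_true(all(diff(pos_counts) <= 0))
  at <- predict(f1, insts)
  expect_equal(at$labels, as.integer(at$probabilities >= 0.5))
})

test_that("dimension mismatches raise shape errors", {
  insts <- separable_instances(2L)
  sc <- fit_schema(insts)
  batch <- batch_graphs(lapply(insts, build_patient_graph, schema = sc))
  params <- edrevisit:::gnn_init_params(ncol(batch$features) + 2L, 4L, 1L)
  expect_error(gnn_forward(batch, params), "dimensions")
  rp <- edrevisit:::rnn_init_params(3L, 4L, 1L)
  expect_error(rnn_forward(matrix(0, 2, 5), rp), "width")
})
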