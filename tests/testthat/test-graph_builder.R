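test_that("the two-visit worked example has the stated nodes and edges", {
  inst <- two_visit_instance()
  sc <- fit_schema(list(inst))
  g <- build_patient_graph(inst, sc)
  # 6 nodes: 2 visit + 2 service + 2 diagnosis
  expect_equal(length(g$node_types), 6L)
  expect_equal(g$node_types,
               c("visit", "visit", "service", "service",
                 "diagnosis", "diagnosis"))
  expect_equal(g$node_names[3:6], c("A", "B", "D1", "D2"))
  # 7 edges: v1-v2; v1-A, v2-A, v2-B; A-D1, A-D2, B-D2
  expect_equal(nrow(g$edges), 7L)
  edge_set <- paste(g$node_names[g$edges$i], g$node_names[g$edges$j])
  expect_setequal(edge_set,
                  c("visit_1 visit_2", "visit_1 A", "visit_2 A",
                    "visit_2 B", "A D1", "A D2", "B D2"))
  # degrees under the node ordering v1,v2,A,B,D1,D2, as implied by the
  # seven listed edges (service A touches v1, v2, D1 and D2)
  expect_equal(rowSums(to_matrices(g)$adjacency), c(2, 3, 4, 2, 1, 2))
  expect_equal(sum(rowSums(to_matrices(g)$adjacency)), 2 * nrow(g$edges))
})

test_that("adjacency is symmetric, binary, zero-diagonal", {
  set.seed(5)
  insts <- small_cohort_instances(40L)
  sc <- fit_schema(insts)
  for (inst in insts[1:15]) {
    A <- to_matrices(build_patient_graph(inst, sc))$adjacency
    expect_equal(A, t(A))
    expect_true(all(A %in% c(0L, 1L)))
    expect_true(all(diag(A) == 0L))
  }
})

test_that("single-visit graph is a 3-node chain without visit-visit edges", {
  inst <- build_instance(make_history(0L))
  sc <- fit_schema(list(inst))
  g <- build_patient_graph(inst, sc)
  expect_equal(length(g$node_types), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sum(g$edges$type == "visit-visit"), 0L)
})

test_that("five visits give exactly four visit-visit edges", {
  h <- make_history(seq(0L, 240L, by = 60L))  # 5 visits as direct input
  inst <- structure(list(patient_id = "P1", input_visits = h, label = 0L),
                    class = "labeled_instance")
  sc <- fit_schema(list(inst))
  g <- build_patient_graph(inst, sc)
  expect_equal(g$n_visits, 5L)
  expect_equal(sum(g$edges$type == "visit-visit"), 4L)
})

test_that("node-count law and connectivity hold on generated instances", {
  set.seed(31)
  insts <- small_cohort_instances(150L, seed = 9L)
  sc <- fit_schema(insts)
  for (inst in insts) {
    g <- build_patient_graph(inst, sc)
    nv <- nrow(inst$input_visits)
    expect_equal(length(g$node_types),
                 nv + length(unique(unlist(inst$input_visits$service_codes))) +
                   length(unique(inst$input_visits$diagnosis_code)))
    expect_equal(sum(g$edges$type == "visit-visit"), nv - 1L)
    # connected: reachability from node 1 spans all nodes
    A <- g$adjacency
    reach <- logical(nrow(A))
    reach[1] <- TRUE
    repeat {
      nxt <- reach | (A %*% reach > 0)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    expect_true(all(reach))
  }
})

test_that("graph construction is deterministic and monotone in visits", {
  set.seed(13)
  h <- random_history(8L)
  cfg <- preprocess_config()
  sc <- fit_schema(list(build_instance(h, cfg)))
  g1 <- build_patient_graph(build_instance(h, cfg), sc)
  g2 <- build_patient_graph(build_instance(h, cfg), sc)
  expect_identical(g1$adjacency, g2$adjacency)
  expect_identical(g1$features, g2$features)
  # adding a visit never shrinks the graph
  counts <- vapply(3:8, function(k) {
    inst <- build_instance(h[seq_len(k), ], cfg)
    g <- build_patient_graph(inst, sc)
    c(nodes = length(g$node_types), edges = nrow(g$edges))
  }, c(nodes = 1, edges = 1))
  expect_true(all(diff(counts["nodes", ]) >= 0))
  expect_true(all(diff(counts["edges", ]) >= 0))
})

test_that("node features carry type indicators and padded blocks", {
  inst <- two_visit_instance()
  sc <- fit_schema(list(inst))
  g <- build_patient_graph(inst, sc)
  X <- to_matrices(g)$features
  # type one-hot in the first three slots
  expect_equal(X[, 1], c(1, 1, 0, 0, 0, 0))
  expect_equal(X[, 2], c(0, 0, 1, 1, 0, 0))
  expect_equal(X[, 3], c(0, 0, 0, 0, 1, 1))
  wv <- 1L + length(sc$triage_levels) + length(sc$disposition_codes)
  expect_equal(ncol(X), 3L + max(wv, length(sc$service_codes),
                                 length(sc$diagnosis_codes)))
  # service node one-hot aligns with schema order
  expect_equal(X[3, 3 + match("A", sc$service_codes)], 1)
  expect_equal(X[5, 3 + match("D1", sc$diagnosis_codes)], 1)
})

test_that("batching is block-diagonal and round-trips", {
  insts <- separable_instances(3L)
  sc <- fit_schema(insts)
  graphs <- lapply(insts, build_patient_graph, schema = sc)
  batch <- batch_graphs(graphs[1:2])
  n1 <- length(graphs[[1]]$node_types)
  n2 <- length(graphs[[2]]$node_types)
  expect_equal(dim(batch$adjacency), c(n1 + n2, n1 + n2))
  # no cross-block edges
  expect_true(all(as.matrix(batch$adjacency[seq_len(n1),
                                            n1 + seq_len(n2)]) == 0))
  expect_identical(unbatch_graphs(batch), graphs[1:2])
  big <- batch_graphs(graphs)
  expect_equal(nrow(big$features),
               sum(vapply(graphs, function(g) length(g$node_types), 1L)))
  expect_error(batch_graphs(list()), "empty")
})

test_that("edge-list dump writes nodes and edges", {
  inst <- two_visit_instance()
  sc <- fit_schema(list(inst))
  g <- build_patient_graph(inst, sc)
  path <- withr::local_tempfile(fileext = ".txt")
  write_graph_edgelist(g, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^#", lines)), 2L)
  expect_equal(length(lines), 2L + 6L + 7L)
})
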