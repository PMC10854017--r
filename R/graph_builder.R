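#' Build the heterogeneous patient graph for one instance
#'
#' Converts a labelled instance into a per-patient graph with three node
#' types and three edge types:
#' \itemize{
#'   \item one \emph{visit} node per input visit, chained in temporal
#'     order (visit t -- visit t+1);
#'   \item one \emph{service} node per distinct service code in the
#'     instance, linked to every visit at which the service occurred;
#'   \item one \emph{diagnosis} node per distinct diagnosis code, linked
#'     to each service node of every visit carrying that diagnosis
#'     (service--diagnosis edges).
#' }
#' Service and diagnosis nodes are shared across visits within the
#' patient graph (one node per distinct code), so a service occurring at
#' two visits bridges both visits' diagnoses. Edges are undirected and
#' there are no self-loops and no direct visit--diagnosis edges.
#'
#' Node features: visit nodes carry `[normalized age, triage one-hot,
#' disposition one-hot]`; service and diagnosis nodes carry their own
#' one-hot. All are zero-padded to a shared width and prefixed with a
#' 3-slot node-type indicator (visit/service/diagnosis) so a single node
#' feature matrix can represent the heterogeneous graph.
#'
#' @param instance A `labeled_instance` (see [build_instance()]).
#' @param schema A fitted [fit_schema()] result.
#' @return A `patient_graph`: list with `node_types`, `node_names`,
#'   `features` (|V| x width matrix), `edges` (data.frame `i`, `j`,
#'   `type` with `i < j`), `adjacency` (|V| x |V| symmetric 0/1 matrix,
#'   zero diagonal), `label`, `n_visits`, `services`, `diagnoses`.
#' @export
build_patient_graph <- function(instance, schema) {
  stopifnot(inherits(instance, "labeled_instance"),
            inherits(schema, "feature_schema"))
  v <- instance$input_visits
  nv <- nrow(v)
  if (nv == 0L) stop("instance has no input visits", call. = FALSE)

  # distinct codes, ordered by schema index (unseen codes last, by code)
  order_codes <- function(codes, vocab) {
    idx <- match(codes, vocab)
    codes[order(is.na(idx), idx, codes, method = "radix")]
  }
  services <- order_codes(unique(unlist(v$service_codes)),
                          schema$service_codes)
  diagnoses <- order_codes(unique(v$diagnosis_code), schema$diagnosis_codes)
  ns <- length(services)
  nd <- length(diagnoses)
  nV <- nv + ns + nd

  svc_id <- function(code) nv + match(code, services)
  dia_id <- function(code) nv + ns + match(code, diagnoses)

  # edges --------------------------------------------------------------
  ei <- integer(0); ej <- integer(0); etype <- character(0)
  if (nv > 1L) {
    ei <- c(ei, seq_len(nv - 1L))
    ej <- c(ej, seq_len(nv - 1L) + 1L)
    etype <- c(etype, rep("visit-visit", nv - 1L))
  }
  for (t in seq_len(nv)) {
    s_nodes <- svc_id(v$service_codes[[t]])
    d_node <- dia_id(v$diagnosis_code[t])
    ei <- c(ei, rep(t, length(s_nodes)), s_nodes)
    ej <- c(ej, s_nodes, rep(d_node, length(s_nodes)))
    etype <- c(etype, rep("visit-service", length(s_nodes)),
               rep("service-diagnosis", length(s_nodes)))
  }
  lo <- pmin(ei, ej); hi <- pmax(ei, ej)
  keep <- !duplicated(cbind(lo, hi))
  edges <- data.frame(i = lo[keep], j = hi[keep], type = etype[keep],
                      stringsAsFactors = FALSE)

  adjacency <- matrix(0L, nV, nV)
  adjacency[cbind(edges$i, edges$j)] <- 1L
  adjacency[cbind(edges$j, edges$i)] <- 1L

  # node features -------------------------------------------------------
  n_tri <- length(schema$triage_levels)
  n_dis <- length(schema$disposition_codes)
  wv <- 1L + n_tri + n_dis
  wf <- 3L + max(wv, length(schema$service_codes),
                 length(schema$diagnosis_codes))
  features <- matrix(0, nV, wf)
  features[seq_len(nv), 1L] <- 1            # type: visit
  if (ns > 0L) features[nv + seq_len(ns), 2L] <- 1    # type: service
  if (nd > 0L) features[nv + ns + seq_len(nd), 3L] <- 1  # type: diagnosis
  features[seq_len(nv), 4L] <- normalize_age(v$age_years, schema)
  ti <- match(v$triage_level, schema$triage_levels)
  ok <- which(!is.na(ti))
  features[cbind(ok, 4L + ti[ok])] <- 1
  di <- match(v$disposition_code, schema$disposition_codes)
  ok <- which(!is.na(di))
  features[cbind(ok, 4L + n_tri + di[ok])] <- 1
  si <- match(services, schema$service_codes)
  ok <- which(!is.na(si))
  features[cbind(nv + ok, 3L + si[ok])] <- 1
  gi <- match(diagnoses, schema$diagnosis_codes)
  ok <- which(!is.na(gi))
  features[cbind(nv + ns + ok, 3L + gi[ok])] <- 1

  structure(list(
    node_types = c(rep("visit", nv), rep("service", ns),
                   rep("diagnosis", nd)),
    node_names = c(paste0("visit_", seq_len(nv)), services, diagnoses),
    features = features,
    edges = edges,
    adjacency = adjacency,
    label = instance$label,
    n_visits = nv,
    services = services,
    diagnoses = diagnoses
  ), class = "patient_graph")
}

#' @export
print.patient_graph <- function(x, ...) {
  cat("patient_graph:", x$n_visits, "visit /", length(x$services),
      "service /", length(x$diagnoses), "diagnosis nodes,",
      nrow(x$edges), "edges, label", x$label, "\n")
  invisible(x)
}

#' Adjacency and node-feature matrices of a patient graph
#'
#' Node ordering is visits in temporal order, then service nodes in
#' schema index order, then diagnosis nodes in schema index order.
#'
#' @param graph A [build_patient_graph()] result.
#' @return List with `adjacency` (symmetric 0/1, zero diagonal) and
#'   `features` (one padded feature row per node).
#' @export
to_matrices <- function(graph) {
  stopifnot(inherits(graph, "patient_graph"))
  list(adjacency = graph$adjacency, features = graph$features)
}

#' Pack patient graphs into a block-diagonal batch
#'
#' Builds the block-diagonal adjacency and stacked feature matrix used
#' for batched message passing, plus the per-graph node index ranges and
#' the mean-readout pooling matrix. [unbatch_graphs()] restores the
#' original list.
#'
#' @param graphs Non-empty list of `patient_graph`.
#' @return A `graph_batch`: list with `adjacency` (sparse block-diagonal),
#'   `features` (stacked matrix), `graph_index` (node -> graph id),
#'   `offsets`, `sizes`, `labels`, `pool` (sparse G x N mean-pool
#'   matrix over all nodes), `pool_visits` (mean-pool over visit nodes
#'   only), and the original `graphs`.
#' @export
batch_graphs <- function(graphs) {
  if (length(graphs) == 0L) stop("empty graph list", call. = FALSE)
  stopifnot(all(vapply(graphs, inherits, TRUE, "patient_graph")))
  sizes <- vapply(graphs, function(g) nrow(g$features), 1L)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  N <- sum(sizes)
  G <- length(graphs)
  adjacency <- Matrix::bdiag(lapply(graphs, function(g)
    Matrix::Matrix(g$adjacency, sparse = TRUE)))
  features <- do.call(rbind, lapply(graphs, function(g) g$features))
  graph_index <- rep(seq_len(G), sizes)
  pool <- Matrix::sparseMatrix(i = graph_index, j = seq_len(N),
                               x = 1 / sizes[graph_index],
                               dims = c(G, N))
  nvis <- vapply(graphs, function(g) g$n_visits, 1L)
  vis_nodes <- unlist(lapply(seq_len(G), function(k)
    offsets[k] + seq_len(nvis[k])))
  pool_visits <- Matrix::sparseMatrix(
    i = rep(seq_len(G), nvis), j = vis_nodes,
    x = 1 / rep(nvis, nvis), dims = c(G, N))
  structure(list(adjacency = adjacency, features = features,
                 graph_index = graph_index, offsets = offsets,
                 sizes = sizes,
                 labels = vapply(graphs, function(g) as.integer(g$label), 1L),
                 pool = pool, pool_visits = pool_visits, graphs = graphs),
            class = "graph_batch")
}

#' Restore the graphs packed by [batch_graphs()]
#' @param batch A `graph_batch`.
#' @return The original list of `patient_graph`.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "graph_batch"))
  batch$graphs
}

#' Dump a patient graph as an edge-list text file
#'
#' Writes a two-section plain-text file (nodes: id, type, name; edges:
#' i, j, type) for inspection.
#'
#' @param graph A `patient_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "patient_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nodes: id\ttype\tname", con)
  writeLines(paste(seq_along(graph$node_types), graph$node_types,
                   graph$node_names, sep = "\t"), con)
  writeLines("# edges: i\tj\ttype", con)
  writeLines(paste(graph$edges$i, graph$edges$j, graph$edges$type,
                   sep = "\t"), con)
  invisible(path)
}
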