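## Local (node-level) graph metrics computed from a learned connectome.
## Degree and clustering follow their binary definitions on the binarized
## post-pruning graph; betweenness, distance and efficiency use edge lengths
## 1/W on the weighted graph. Shortest-path machinery is igraph's; the local
## assortativity decomposition is implemented here.

.metric_matrix <- function(x) {
  W <- if (is(x, "Connectome")) connectomeMatrix(x) else as.matrix(x)
  ok <- .check_sym_nonneg(unname(W), "connectome matrix")
  if (!isTRUE(ok)) stop(ok)
  unname(W)
}

.length_graph <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Node metrics of a connectome
#'
#' Six local graph metrics, each returning one value per node:
#' \describe{
#'   \item{`nodeDegree`}{number of incident edges on the binarized graph.}
#'   \item{`clusteringCoefficient`}{`2 E_i / (K_i (K_i - 1))` on the
#'     binarized graph, 0 when `K_i < 2`.}
#'   \item{`betweennessCentrality`}{sum over ordered pairs `j != k != i` of
#'     the fraction of shortest paths through `i`, with edge lengths
#'     `1/W`; unnormalized unless `normalized = TRUE` (divisor
#'     `(N-1)(N-2)`).}
#'   \item{`localDistance`}{mean shortest-path length (edge lengths `1/W`)
#'     from the node to every *reachable* other node; 0 when none is
#'     reachable.}
#'   \item{`localEfficiency`}{mean inverse shortest-path length among the
#'     node's neighbours within their induced subgraph (lengths `1/W`);
#'     unreachable pairs contribute 0; 0 when `K_i < 2`.}
#'   \item{`localAssortativity`}{excess-degree decomposition
#'     `r_i = j_i (j_i + 1)(kbar_i - mu_q) / (2 M sigma_q^2)` on the
#'     binarized graph, whose node sum equals the global degree
#'     assortativity; 0 for all nodes when the stub variance vanishes
#'     (regular graphs).}
#' }
#'
#' @param x a `Connectome` or a symmetric nonnegative weight matrix.
#' @param ... passed through (only `betweennessCentrality` takes
#'   `normalized`).
#' @return Numeric vector of length N.
#' @name nodeMetrics
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
#' betweennessCentrality(W)  # (0, 2, 0): ordered pairs through the middle
NULL

#' @rdname nodeMetrics
#' @export
setMethod("nodeDegree", "matrix", function(x, ...) {
  W <- .metric_matrix(x)
  colSums(W > 0)
})

#' @rdname nodeMetrics
#' @export
setMethod("nodeDegree", "Connectome",
          function(x, ...) nodeDegree(connectomeMatrix(x)))

#' @rdname nodeMetrics
#' @export
setMethod("clusteringCoefficient", "matrix", function(x, ...) {
  W <- .metric_matrix(x)
  A <- (W > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  cc
})

#' @rdname nodeMetrics
#' @export
setMethod("clusteringCoefficient", "Connectome",
          function(x, ...) clusteringCoefficient(connectomeMatrix(x)))

#' @rdname nodeMetrics
#' @param normalized divide by `(N - 1)(N - 2)` (off by default).
#' @export
setMethod("betweennessCentrality", "matrix",
          function(x, normalized = FALSE, ...) {
  W <- .metric_matrix(x)
  n <- nrow(W)
  if (!any(W > 0)) return(numeric(n))
  g <- .length_graph(W)
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = igraph::E(g)$length)
  b <- 2 * b  # ordered pairs
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2))
  unname(b)
})

#' @rdname nodeMetrics
#' @export
setMethod("betweennessCentrality", "Connectome",
          function(x, normalized = FALSE, ...)
            betweennessCentrality(connectomeMatrix(x),
                                  normalized = normalized))

#' @rdname nodeMetrics
#' @export
setMethod("localDistance", "matrix", function(x, ...) {
  W <- .metric_matrix(x)
  n <- nrow(W)
  if (!any(W > 0)) return(numeric(n))
  g <- .length_graph(W)
  D <- igraph::distances(g, weights = igraph::E(g)$length)
  diag(D) <- NA
  out <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else mean(d)
  }, numeric(1))
  if (any(!is.finite(D[upper.tri(D)])) &&
      isTRUE(getOption("SparseConnectome.verbose", FALSE)))
    .msg("graph is disconnected; unreachable nodes excluded from ",
         "localDistance means", level = "warn")
  out
})

#' @rdname nodeMetrics
#' @export
setMethod("localDistance", "Connectome",
          function(x, ...) localDistance(connectomeMatrix(x)))

#' @rdname nodeMetrics
#' @export
setMethod("localEfficiency", "matrix", function(x, ...) {
  W <- .metric_matrix(x)
  n <- nrow(W)
  A <- W > 0
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    Wsub <- W[nb, nb, drop = FALSE]
    if (!any(Wsub > 0)) return(0)
    gs <- .length_graph(Wsub)
    D <- igraph::distances(gs, weights = igraph::E(gs)$length)
    inv <- 1 / D
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
})

#' @rdname nodeMetrics
#' @export
setMethod("localEfficiency", "Connectome",
          function(x, ...) localEfficiency(connectomeMatrix(x)))

#' @rdname nodeMetrics
#' @export
setMethod("localAssortativity", "matrix", function(x, ...) {
  W <- .metric_matrix(x)
  n <- nrow(W)
  A <- (W > 0) * 1
  K <- colSums(A)
  M <- sum(A) / 2
  if (M < 1) stop("graph has no edges")
  # remaining-degree distribution over the 2M edge stubs
  mu_q <- sum(K * (K - 1)) / (2 * M)
  var_q <- sum(K * (K - 1)^2) / (2 * M) - mu_q^2
  if (var_q <= 1e-12) return(numeric(n))
  kbar <- as.numeric(A %*% (K - 1))
  kbar <- ifelse(K > 0, kbar / pmax(K, 1), 0)
  r <- (K - 1) * K * (kbar - mu_q) / (2 * M * var_q)
  r[K == 0] <- 0
  r
})

#' @rdname nodeMetrics
#' @export
setMethod("localAssortativity", "Connectome",
          function(x, ...) localAssortativity(connectomeMatrix(x)))

#' Metric names computed by [computeAllMetrics()]
#' @return Character vector of the six local metric names.
#' @export
metricNames <- function() {
  c("assortativity", "betweenness", "clustering", "distance", "degree",
    "efficiency")
}

.metric_fun <- function(name) {
  switch(name,
         assortativity = localAssortativity,
         betweenness = betweennessCentrality,
         clustering = clusteringCoefficient,
         distance = localDistance,
         degree = nodeDegree,
         efficiency = localEfficiency,
         stop("unknown metric: ", name))
}

#' Compute all six local metrics for a cohort of connectomes
#'
#' @param connectomes list of `Connectome` objects sharing the same node
#'   count.
#' @param groups optional group labels (one per connectome), stored in
#'   `colData`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay per
#'   metric (rows = nodes, columns = subjects) and subject id / group in
#'   `colData`.
#' @export
computeAllMetrics <- function(connectomes, groups = NULL) {
  stopifnot(length(connectomes) >= 1L)
  ns <- vapply(connectomes, function(cn) nrow(connectomeMatrix(cn)),
               integer(1))
  if (length(unique(ns)) != 1L)
    stop("all connectomes must share the same node count")
  n <- ns[1L]
  ids <- vapply(connectomes, subjectID, character(1))
  assays <- lapply(metricNames(), function(m) {
    f <- .metric_fun(m)
    mat <- vapply(connectomes, function(cn) as.numeric(f(cn)), numeric(n))
    dimnames(mat) <- list(sprintf("node_%d", seq_len(n) - 1L), ids)
    mat
  })
  names(assays) <- metricNames()
  cd <- S4Vectors::DataFrame(subject_id = ids)
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(connectomes))
    cd$group <- as.character(groups)
  }
  SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd)
}

#' Extract one metric as a subjects x nodes matrix
#'
#' @param se the [computeAllMetrics()] result.
#' @param metric one of [metricNames()].
#' @return Numeric matrix, rows = subjects, columns = nodes.
#' @export
metricTable <- function(se, metric) {
  metric <- match.arg(metric, metricNames())
  t(SummarizedExperiment::assay(se, metric))
}
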