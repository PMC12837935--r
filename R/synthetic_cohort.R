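## Synthetic cohort generator: ground-truth graphs with planted nodal-degree
## effects, and smooth graph signals simulated on them.

# RMS amplitude of the filtered signal before observation noise is added.
# With T = 140 this puts pairwise squared distances at O(10), where the
# unit-regularized graph learner returns graphs of density comparable to the
# generating template (see the methods vignette).
.SIGNAL_RMS <- 0.3

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.is_connected_adj <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Random-geometric template graph
#'
#' Draws node positions uniformly on the unit square and connects pairs
#' closer than a radius chosen to give mean degree near `targetDegree`;
#' redraws until the graph is connected. Edge weights are drawn uniformly
#' from `spec`'s `edgeWeightRange`. The template is shared by all subjects
#' of a cohort.
#'
#' @param spec a [cohortSpec()].
#' @param targetDegree desired mean degree of the template.
#' @param maxRetries positions are redrawn at most this many times.
#' @return Weighted adjacency matrix (symmetric, zero diagonal).
#' @export
makeTemplateGraph <- function(spec, targetDegree = 6, maxRetries = 100) {
  n <- spec@nNodes
  r <- sqrt(targetDegree / (n * pi)) * 1.1  # 1.1 offsets boundary losses
  for (try in seq_len(maxRetries)) {
    xy <- matrix(runif(2 * n), n, 2)
    D <- as.matrix(dist(xy))
    A <- D < r
    diag(A) <- FALSE
    if (!.is_connected_adj(A)) next
    W <- matrix(0, n, n)
    iu <- which(A & upper.tri(A))
    W[iu] <- runif(length(iu), spec@edgeWeightRange[1],
                   spec@edgeWeightRange[2])
    return(W + t(W))
  }
  stop("could not draw a connected geometric template in ", maxRetries,
       " attempts")
}

# Degree-preserving rewiring: `nswaps` double-edge swaps; weights travel
# with the rewired edges so the weighted degree sequence changes only
# through which stubs are paired.
.double_edge_swaps <- function(W, nswaps) {
  if (nswaps < 1L) return(W)
  el <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  M <- nrow(el)
  for (s in seq_len(nswaps)) {
    for (att in 1:100) {
      e <- sample.int(M, 2L)
      a <- el[e[1L], 1L]; b <- el[e[1L], 2L]
      cc <- el[e[2L], 1L]; d <- el[e[2L], 2L]
      if (length(unique(c(a, b, cc, d))) < 4L) next
      if (W[a, d] > 0 || W[cc, b] > 0) next
      wa <- W[a, b]; wc <- W[cc, d]
      W[a, b] <- W[b, a] <- 0
      W[cc, d] <- W[d, cc] <- 0
      W[a, d] <- W[d, a] <- wa
      W[cc, b] <- W[b, cc] <- wc
      el[e[1L], ] <- c(min(a, d), max(a, d))
      el[e[2L], ] <- c(min(cc, b), max(cc, b))
      break
    }
  }
  W
}

#' Ground-truth graph for one subject
#'
#' Starts from a template shared by the whole cohort, rewires a fraction
#' `spec@subjectJitter` of its edges by degree-preserving double-edge swaps,
#' and, for case-group subjects, attaches `spec@plantedExtraEdges` extra
#' edges from each planted node to uniformly chosen non-neighbours outside
#' the planted set. The expected binarized degree at planted nodes therefore
#' differs between groups by exactly `plantedExtraEdges`, while the jitter
#' keeps non-planted degree sequences matched up to the added edge
#' endpoints.
#'
#' Uses the ambient RNG stream; seed it (or call via [generateCohort()]) for
#' reproducibility.
#'
#' @param spec a [cohortSpec()].
#' @param group `"case"` (receives the planted effect) or `"control"`.
#' @param subjectID identifier stored in the result.
#' @param template optional weighted adjacency matrix to use as template;
#'   drawn with [makeTemplateGraph()] when `NULL`.
#' @param maxRetries rewiring is retried at most this many times if it
#'   disconnects the graph.
#' @return A `GroundTruthGraph`.
#' @export
makeGroundTruthGraph <- function(spec, group = c("case", "control"),
                                 subjectID = "subject", template = NULL,
                                 maxRetries = 50) {
  group <- match.arg(group)
  if (is.null(template)) template <- makeTemplateGraph(spec)
  M <- sum(template[upper.tri(template)] > 0)
  nswaps <- round(spec@subjectJitter * M)
  W <- NULL
  for (try in seq_len(maxRetries)) {
    Wj <- .double_edge_swaps(template, nswaps)
    if (.is_connected_adj(Wj)) { W <- Wj; break }
  }
  if (is.null(W))
    stop("subject-level rewiring disconnected the graph in all ",
         maxRetries, " attempts")
  if (group == "case" && spec@plantedExtraEdges > 0L) {
    for (p in spec@plantedNodes) {
      cand <- setdiff(which(W[p, ] == 0), c(p, spec@plantedNodes))
      if (length(cand) < spec@plantedExtraEdges)
        stop("planted node ", p, " has too few non-neighbours to receive ",
             spec@plantedExtraEdges, " extra edges")
      add <- cand[sample.int(length(cand), spec@plantedExtraEdges)]
      W[p, add] <- W[add, p] <-
        runif(length(add), spec@edgeWeightRange[1], spec@edgeWeightRange[2])
    }
  }
  new("GroundTruthGraph", adjacency = W, subjectID = subjectID,
      group = group)
}

#' Simulate smooth graph signals on a ground-truth graph
#'
#' Each timepoint is an independent draw of the low-pass graph filter
#' \eqn{(I + \tau L)^{-1}} applied to an N-vector of standard white noise,
#' where L is the combinatorial Laplacian of the (weighted) graph; additive
#' observation noise of standard deviation `noiseSD` is then superimposed.
#' Rows are timepoints, columns are nodes. The underlying noise is drawn as
#' a single N x `nTimepoints` standard-normal matrix, so as
#' \eqn{\tau \to 0} with `noiseSD = 0` the output reproduces that draw.
#'
#' Timepoints are i.i.d. (no temporal autocorrelation): the downstream graph
#' learner only consumes pairwise time-series distances, which depend on the
#' spatial covariance, not on temporal order.
#'
#' @param graph a `GroundTruthGraph` or a weighted adjacency matrix; must be
#'   connected.
#' @param nTimepoints number of rows to simulate.
#' @param smoothingTau positive filter strength.
#' @param noiseSD standard deviation of additive observation noise.
#' @param targetRMS if non-`NULL`, the filtered (pre-noise) signal is
#'   rescaled to this root-mean-square amplitude; [generateCohort()] uses a
#'   fixed design value so that pairwise distances land in the regime the
#'   unit-regularized learner expects.
#' @return A T x N numeric matrix.
#' @export
simulateSmoothSignals <- function(graph, nTimepoints, smoothingTau,
                                  noiseSD = 0, targetRMS = NULL) {
  W <- if (is(graph, "GroundTruthGraph")) adjacencyMatrix(graph) else
    as.matrix(graph)
  if (smoothingTau <= 0) stop("smoothingTau must be > 0")
  if (!.is_connected_adj(W)) stop("graph must be connected")
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  E <- matrix(rnorm(n * nTimepoints), n, nTimepoints)
  X <- t(solve(diag(n) + smoothingTau * L, E))
  if (!is.null(targetRMS)) X <- X / sqrt(mean(X^2)) * targetRMS
  if (noiseSD > 0) X <- X + noiseSD * matrix(rnorm(nTimepoints * n),
                                             nTimepoints, n)
  colnames(X) <- sprintf("node_%d", seq_len(n) - 1L)
  X
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `spec` (including its seed): draws one template graph,
#' then per subject a jittered (and, for cases, planted) ground-truth graph
#' and a smooth-signal time-series matrix. Case subjects come first. The
#' phenotype table carries age and sex fillers (normal / Bernoulli draws)
#' that the pipeline core never uses.
#'
#' @param spec a [cohortSpec()].
#' @return A list with elements `timeSeries` (list of
#'   [subjectTimeSeries()]), `phenotype` (data.frame with subject_id, group,
#'   age, sex), and `graphs` (list of `GroundTruthGraph`).
#' @examples
#' coh <- generateCohort(cohortSpec(nNodes = 20, nGroupA = 3, nGroupB = 3,
#'                                  nTimepoints = 60))
#' length(coh$timeSeries)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  .with_seed(spec@seed, {
    template <- makeTemplateGraph(spec)
    nsub <- spec@nGroupA + spec@nGroupB
    groups <- rep(c("case", "control"), c(spec@nGroupA, spec@nGroupB))
    ids <- sprintf("sub-%03d", seq_len(nsub))
    graphs <- vector("list", nsub)
    tslist <- vector("list", nsub)
    for (s in seq_len(nsub)) {
      g <- makeGroundTruthGraph(spec, groups[s], ids[s], template = template)
      X <- simulateSmoothSignals(g, spec@nTimepoints, spec@smoothingTau,
                                 spec@noiseSD, targetRMS = .SIGNAL_RMS)
      graphs[[s]] <- g
      tslist[[s]] <- subjectTimeSeries(X, ids[s], groups[s])
    }
    phenotype <- data.frame(
      subject_id = ids,
      group = groups,
      age = round(pmax(6, rnorm(nsub, mean = 15, sd = 6.5)), 1),
      sex = ifelse(rbinom(nsub, 1L, 0.8) == 1L, "M", "F"),
      stringsAsFactors = FALSE)
    list(timeSeries = tslist, phenotype = phenotype, graphs = graphs)
  })
}
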