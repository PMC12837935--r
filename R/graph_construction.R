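## Subject-specific sparse connectome learning: pairwise squared distances,
## log-degree graph learning (primal-dual solver in src/), and the fixed
## rescale -> symmetrize -> prune post-processing.

#' Parameters of the graph-learning stage
#'
#' `alpha` weights the log-degree barrier (larger values force larger node
#' degrees), `beta` the Frobenius penalty controlling weight spread. The
#' learned weights are rescaled by `delta`, symmetrized, and entries below
#' `pruneThreshold` are zeroed. Defaults are the literature-fixed operating
#' point: alpha = beta = 1, delta = 2, threshold 0.03.
#'
#' @param alpha,beta positive regularization weights.
#' @param delta positive rescale factor applied before pruning.
#' @param pruneThreshold nonnegative pruning cutoff; entries strictly below
#'   it (including any negatives) are set to zero.
#' @param tol solver tolerance: converged when the relative objective
#'   change and the relative change of the active (non-vanishing) iterates
#'   both fall below `tol`; edges below 1e-3 of the largest weight are
#'   treated as numerically zero for the iterate criterion, since boundary
#'   edges decay sublinearly.
#' @param maxIter iteration cap (generous: iterations are cheap); the solver
#'   errors if it is reached before
#'   `tol` is met.
#' @param standardizeROIs if `TRUE`, columns are centred and scaled to unit
#'   standard deviation before distances are computed (raw amplitudes are
#'   used by default).
#' @return A classed list of validated parameters.
#' @export
graphLearningParams <- function(alpha = 1, beta = 1, delta = 2,
                                pruneThreshold = 0.03, tol = 1e-6,
                                maxIter = 50000, standardizeROIs = FALSE) {
  stopifnot(alpha > 0, beta > 0, delta > 0, pruneThreshold >= 0,
            tol > 0, maxIter >= 1)
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 pruneThreshold = pruneThreshold, tol = tol,
                 maxIter = as.integer(maxIter),
                 standardizeROIs = isTRUE(standardizeROIs)),
            class = "GraphLearningParams")
}

#' Pairwise squared Euclidean distances between regional time series
#'
#' `Z[i, j] = ||x_i - x_j||^2` over the T samples of columns i and j.
#'
#' @param ts a [subjectTimeSeries()] or a T x N numeric matrix.
#' @param standardizeROIs centre and scale each column first; errors on a
#'   constant column.
#' @return Symmetric nonnegative N x N matrix with zero diagonal.
#' @examples
#' pairwiseSqDistances(cbind(c(1, 0), c(0, 1)))
#' @export
pairwiseSqDistances <- function(ts, standardizeROIs = FALSE) {
  X <- if (is(ts, "SubjectTimeSeries")) tsMatrix(ts) else as.matrix(ts)
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("need at least 2 timepoints and 2 regions")
  if (any(!is.finite(X))) stop("time series contain missing values")
  if (standardizeROIs) {
    s <- apply(X, 2L, sd)
    if (any(s == 0))
      stop("cannot standardize: constant column(s) ",
           paste(which(s == 0), collapse = ", "))
    X <- scale(X)
  }
  Z <- as.matrix(dist(t(X)))^2
  dimnames(Z) <- NULL
  diag(Z) <- 0
  Z
}

# edge indexing of the upper triangle, column-major (matches upper.tri())
.edge_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ut[, 1L], j = ut[, 2L])
}

#' Learn a graph from pairwise distances with a log-degree barrier
#'
#' Minimizes, over symmetric nonnegative zero-diagonal W,
#' \deqn{\|W \circ Z\|_{1,1} - \alpha \sum_i \log d_i + \beta \|W\|_F^2,}
#' with \eqn{d_i = \sum_j W_{ij}}, by a deterministic primal-dual
#' (forward-backward-forward) splitting on the upper-triangle weight vector.
#' The log barrier guarantees strictly positive degrees at the optimum.
#'
#' @param Z symmetric nonnegative distance matrix with zero diagonal (see
#'   [pairwiseSqDistances()]).
#' @param params a [graphLearningParams()].
#' @return The raw learned weight matrix (before rescaling/pruning), with
#'   attributes `iterations`, `objective` and `rel_change`.
#' @examples
#' Z <- matrix(c(0, 1, 1, 0), 2, 2)
#' learnGraphLogDegrees(Z)[1, 2]  # closed form: 0.5
#' @export
learnGraphLogDegrees <- function(Z, params = graphLearningParams()) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n != ncol(Z) || n < 2L) stop("Z must be square with N >= 2")
  if (any(!is.finite(Z)) || any(Z < 0)) stop("Z must be finite nonnegative")
  if (max(abs(Z - t(Z))) > 1e-8) stop("Z must be symmetric")
  idx <- .edge_index(n)
  z <- Z[upper.tri(Z)]
  # exact normalization: with Z = c * Zt, the minimizer satisfies
  # W*(Z, alpha, beta) = U*(Zt, alpha, beta / c^2) / c. Solving in
  # normalized units (mean distance 1) conditions the primal-dual iteration
  # dramatically better for large or small distance scales.
  c0 <- mean(z)
  if (!is.finite(c0) || c0 <= 0) c0 <- 1
  res <- .fbf_log_degree(z / c0, idx$i - 1L, idx$j - 1L, n,
                         params$alpha, params$beta / c0^2, params$tol,
                         params$maxIter)
  if (!res$converged)
    stop(sprintf(paste0("graph learning did not converge in %d iterations ",
                        "(final relative objective change %.3g, iterate ",
                        "change %.3g)"),
                 params$maxIter, res$rel_change, res$rel_iterate_change))
  if (min(res$degrees) <= 0)
    stop("solver exited with a nonpositive degree; log barrier violated")
  w <- res$w / c0
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- w
  W <- W + t(W)
  d <- rowSums(W)
  obj <- 2 * sum(z * w) - params$alpha * sum(log(d)) +
    2 * params$beta * sum(w^2)
  structure(W, iterations = res$iterations, objective = obj,
            rel_change = res$rel_change)
}

#' Rescale, symmetrize and prune a learned weight matrix
#'
#' Fixed order: `W <- delta * W`, then `W <- (W + t(W)) / 2`, then entries
#' strictly below `pruneThreshold` (including any negatives) are zeroed and
#' the diagonal is forced to zero.
#'
#' @param W_raw square numeric matrix.
#' @param params a [graphLearningParams()].
#' @param subjectID identifier stored in the result.
#' @return A `Connectome`.
#' @export
postprocessConnectome <- function(W_raw, params = graphLearningParams(),
                                  subjectID = "subject") {
  W <- as.matrix(W_raw)
  if (nrow(W) != ncol(W)) stop("W_raw must be square")
  W <- params$delta * W
  W <- (W + t(W)) / 2
  W[W < params$pruneThreshold] <- 0
  diag(W) <- 0
  new("Connectome", W = unname(W), subjectID = as.character(subjectID),
      params = unclass(params))
}

#' Build a subject's sparse connectome from its time series
#'
#' Composition of [pairwiseSqDistances()], [learnGraphLogDegrees()] and
#' [postprocessConnectome()]; deterministic (the solver has a fixed
#' initialization).
#'
#' @param ts a [subjectTimeSeries()] or T x N matrix.
#' @param params a [graphLearningParams()].
#' @param subjectID identifier; taken from `ts` when it is a
#'   `SubjectTimeSeries`.
#' @return A `Connectome`.
#' @export
buildConnectome <- function(ts, params = graphLearningParams(),
                            subjectID = NULL) {
  if (is.null(subjectID))
    subjectID <- if (is(ts, "SubjectTimeSeries")) subjectID(ts) else
      "subject"
  Z <- pairwiseSqDistances(ts, standardizeROIs = params$standardizeROIs)
  W_raw <- learnGraphLogDegrees(Z, params)
  cn <- postprocessConnectome(W_raw, params, subjectID)
  if (isTRUE(getOption("SparseConnectome.verbose", FALSE)))
    .msg(sprintf("%s: %d iterations, objective %.4f",
                 subjectID, attr(W_raw, "iterations"),
                 attr(W_raw, "objective")))
  cn
}

#' @rdname buildConnectome
#' @param tsList list of [subjectTimeSeries()].
#' @export
buildConnectomes <- function(tsList, params = graphLearningParams()) {
  lapply(tsList, buildConnectome, params = params)
}
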