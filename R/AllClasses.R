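#' @include AllGenerics.R
NULL

## Central S4 data objects: cohort specification, ground-truth graphs,
## subject time series, learned connectomes, node-selection results and
## cross-validation results. Metric tables live in a SummarizedExperiment
## (nodes x subjects, one assay per metric) rather than a bespoke class.

.check_sym_nonneg <- function(W, what = "matrix") {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    return(sprintf("%s must be a square matrix", what))
  if (any(!is.finite(W)))
    return(sprintf("%s contains non-finite values", what))
  if (max(abs(W - t(W))) > 1e-8)
    return(sprintf("%s must be symmetric", what))
  if (any(W < 0))
    return(sprintf("%s must be nonnegative", what))
  if (any(diag(W) != 0))
    return(sprintf("%s must have a zero diagonal", what))
  TRUE
}

# ---------------------------------------------------------------------------
# CohortSpec

#' @rdname cohortSpec
#' @export
setClass("CohortSpec",
  representation(
    nNodes = "integer", nTimepoints = "integer",
    nGroupA = "integer", nGroupB = "integer",
    plantedNodes = "integer", plantedExtraEdges = "integer",
    edgeWeightRange = "numeric", subjectJitter = "numeric",
    noiseSD = "numeric", smoothingTau = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nNodes < 4L) msg <- c(msg, "nNodes must be >= 4")
    if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
    if (object@nGroupA < 2L || object@nGroupB < 2L)
      msg <- c(msg, "both groups need at least 2 subjects")
    if (length(object@plantedNodes) &&
        (any(object@plantedNodes < 1L) ||
         any(object@plantedNodes > object@nNodes) ||
         anyDuplicated(object@plantedNodes)))
      msg <- c(msg, "plantedNodes must be distinct indices in 1..nNodes")
    if (object@plantedExtraEdges < 0L)
      msg <- c(msg, "plantedExtraEdges must be >= 0")
    if (length(object@edgeWeightRange) != 2L ||
        any(object@edgeWeightRange <= 0) ||
        diff(object@edgeWeightRange) < 0)
      msg <- c(msg, "edgeWeightRange must be an increasing positive interval")
    if (object@subjectJitter < 0 || object@subjectJitter > 1)
      msg <- c(msg, "subjectJitter must be in [0, 1]")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
    if (object@smoothingTau <= 0) msg <- c(msg, "smoothingTau must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of subjects in two groups ("case" and "control") whose
#' ground-truth connectivity graphs share a random-geometric template but
#' differ, in the case group, by `plantedExtraEdges` additional edges at each
#' of the `plantedNodes`. Regional signals are simulated as smooth graph
#' signals on each subject's ground-truth graph (see
#' [simulateSmoothSignals()]).
#'
#' Defaults mirror a single-site resting-state cohort: 74 cases and 98
#' controls, 140 timepoints per subject (the minimum scan length accepted by
#' [loadCohort()]), and a 50-node parcellation kept small enough that a full
#' cohort can be generated and analysed in seconds.
#'
#' @param nNodes number of graph nodes (regions).
#' @param nTimepoints number of timepoints per subject.
#' @param nGroupA,nGroupB number of case / control subjects.
#' @param plantedNodes indices (1-based) of nodes carrying the group effect.
#' @param plantedExtraEdges extra edges attached to each planted node in
#'   case-group graphs; 0 yields a null cohort with no group difference.
#' @param edgeWeightRange interval from which edge weights are drawn.
#' @param subjectJitter fraction of template edges rewired per subject by
#'   degree-preserving double-edge swaps.
#' @param noiseSD standard deviation of additive observation noise.
#' @param smoothingTau low-pass filter strength; each timepoint is
#'   \eqn{(I + \tau L)^{-1}} applied to white noise.
#' @param seed integer seed making [generateCohort()] a pure function of the
#'   spec.
#' @return A `CohortSpec` object.
#' @examples
#' spec <- cohortSpec(nNodes = 20, nGroupA = 4, nGroupB = 4)
#' @export
cohortSpec <- function(nNodes = 50, nTimepoints = 140,
                       nGroupA = 74, nGroupB = 98,
                       plantedNodes = 1:5, plantedExtraEdges = 3,
                       edgeWeightRange = c(0.5, 1.5),
                       subjectJitter = 0.05, noiseSD = 0.02,
                       smoothingTau = 5, seed = 1) {
  new("CohortSpec",
      nNodes = as.integer(nNodes), nTimepoints = as.integer(nTimepoints),
      nGroupA = as.integer(nGroupA), nGroupB = as.integer(nGroupB),
      plantedNodes = as.integer(plantedNodes),
      plantedExtraEdges = as.integer(plantedExtraEdges),
      edgeWeightRange = as.numeric(edgeWeightRange),
      subjectJitter = as.numeric(subjectJitter),
      noiseSD = as.numeric(noiseSD),
      smoothingTau = as.numeric(smoothingTau),
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nNodes, "nodes,",
      object@nGroupA, "case +", object@nGroupB, "control subjects,",
      object@nTimepoints, "timepoints\n")
  cat("  planted nodes:", paste(object@plantedNodes, collapse = ", "),
      sprintf("(+%d edges each in cases)\n", object@plantedExtraEdges))
  cat(sprintf("  jitter %.3f, noise sd %.3f, tau %.2f, seed %d\n",
              object@subjectJitter, object@noiseSD, object@smoothingTau,
              object@seed))
})

# ---------------------------------------------------------------------------
# GroundTruthGraph

#' @rdname makeGroundTruthGraph
#' @export
setClass("GroundTruthGraph",
  representation(adjacency = "matrix", subjectID = "character",
                 group = "character"),
  validity = function(object) {
    ok <- .check_sym_nonneg(object@adjacency, "adjacency")
    if (!isTRUE(ok)) return(ok)
    TRUE
  })

setMethod("show", "GroundTruthGraph", function(object) {
  A <- object@adjacency
  cat(sprintf("GroundTruthGraph '%s' (%s): %d nodes, %d edges\n",
              object@subjectID, object@group, nrow(A),
              sum(A[upper.tri(A)] > 0)))
})

#' @export
setMethod("adjacencyMatrix", "GroundTruthGraph",
          function(x) x@adjacency)
#' @export
setMethod("subjectID", "GroundTruthGraph", function(x) x@subjectID)
#' @export
setMethod("groupLabel", "GroundTruthGraph", function(x) x@group)

# ---------------------------------------------------------------------------
# SubjectTimeSeries

#' Container for one subject's regional time series
#'
#' A T x N matrix (rows = timepoints, columns = nodes/regions) together with
#' a subject identifier and a group label.
#'
#' @param ts numeric T x N matrix.
#' @param subjectID subject identifier.
#' @param group group label.
#' @return A `SubjectTimeSeries` object.
#' @export
subjectTimeSeries <- function(ts, subjectID, group = NA_character_) {
  new("SubjectTimeSeries", ts = as.matrix(ts),
      subjectID = as.character(subjectID), group = as.character(group))
}

#' @rdname subjectTimeSeries
#' @export
setClass("SubjectTimeSeries",
  representation(ts = "matrix", subjectID = "character",
                 group = "character"),
  validity = function(object) {
    if (!is.numeric(object@ts)) return("ts must be numeric")
    if (any(!is.finite(object@ts))) return("ts contains non-finite values")
    if (nrow(object@ts) < 2L || ncol(object@ts) < 2L)
      return("ts must have at least 2 timepoints and 2 nodes")
    TRUE
  })

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s' (%s): %d timepoints x %d nodes\n",
              object@subjectID, object@group,
              nrow(object@ts), ncol(object@ts)))
})

#' @export
setMethod("tsMatrix", "SubjectTimeSeries", function(x) x@ts)
#' @export
setMethod("subjectID", "SubjectTimeSeries", function(x) x@subjectID)
#' @export
setMethod("groupLabel", "SubjectTimeSeries", function(x) x@group)

# ---------------------------------------------------------------------------
# Connectome

#' @rdname buildConnectome
#' @export
setClass("Connectome",
  representation(W = "matrix", subjectID = "character", params = "list"),
  validity = function(object) {
    ok <- .check_sym_nonneg(object@W, "W")
    if (!isTRUE(ok)) return(ok)
    thr <- object@params$pruneThreshold
    if (!is.null(thr) && is.finite(thr)) {
      nz <- object@W[object@W > 0]
      if (length(nz) && min(nz) < thr)
        return("nonzero weights below the prune threshold")
    }
    TRUE
  })

setMethod("show", "Connectome", function(object) {
  W <- object@W
  m <- sum(W[upper.tri(W)] > 0)
  cat(sprintf("Connectome '%s': %d nodes, %d edges (density %.3f)\n",
              object@subjectID, nrow(W), m,
              m / choose(nrow(W), 2)))
})

#' @export
setMethod("connectomeMatrix", "Connectome", function(x) x@W)
#' @export
setMethod("subjectID", "Connectome", function(x) x@subjectID)

# ---------------------------------------------------------------------------
# NodeSelection

#' @rdname selectFeatures
#' @export
setClass("NodeSelection",
  representation(metric = "character", table = "data.frame",
                 selected = "integer", k = "integer", q = "numeric"),
  validity = function(object) {
    need <- c("node", "t", "dof", "p_raw", "p_adjusted", "significant",
              "rank")
    if (!all(need %in% names(object@table)))
      return("selection table is missing required columns")
    tb <- object@table
    if (any(tb$p_adjusted + 1e-12 < tb$p_raw))
      return("adjusted p-values must be >= raw p-values")
    if (!setequal(tb$rank, seq_len(nrow(tb))))
      return("ranks must be a permutation of 1..N")
    TRUE
  })

setMethod("show", "NodeSelection", function(object) {
  cat(sprintf("NodeSelection (%s): %d nodes tested, %d significant at q = %g\n",
              object@metric, nrow(object@table),
              sum(object@table$significant), object@q))
  cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

#' @export
setMethod("selectionTable", "NodeSelection", function(x) x@table)
#' @export
setMethod("selectedNodes", "NodeSelection", function(x) x@selected)

# ---------------------------------------------------------------------------
# CVResult

#' @rdname loocvEvaluate
#' @export
setClass("CVResult",
  representation(metric = "character", mode = "character", k = "integer",
                 predictions = "data.frame", confusion = "numeric",
                 performance = "numeric", foldNodes = "list"),
  validity = function(object) {
    cc <- object@confusion
    if (!all(c("TP", "FP", "TN", "FN") %in% names(cc)))
      return("confusion must contain TP, FP, TN, FN")
    if (sum(cc) != nrow(object@predictions))
      return("confusion counts must sum to the number of subjects")
    TRUE
  })

setMethod("show", "CVResult", function(object) {
  p <- object@performance
  cat(sprintf("CVResult (%s, %s selection, k = %d): n = %d\n",
              object@metric, object@mode, object@k,
              nrow(object@predictions)))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f, precision %.3f, F1 %.3f\n",
              p["accuracy"], p["sensitivity"], p["specificity"],
              p["precision"], p["f1"]))
})

#' @export
setMethod("confusionCounts", "CVResult", function(x) x@confusion)
#' @export
setMethod("performanceMetrics", "CVResult", function(x) x@performance)
#' @export
setMethod("foldPredictions", "CVResult", function(x) x@predictions)
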