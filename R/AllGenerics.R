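#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @export
setGeneric("connectomeMatrix", function(x) standardGeneric("connectomeMatrix"))

#' @export
setGeneric("nodeDegree", function(x, ...) standardGeneric("nodeDegree"))

#' @export
setGeneric("clusteringCoefficient",
           function(x, ...) standardGeneric("clusteringCoefficient"))

#' @export
setGeneric("betweennessCentrality",
           function(x, ...) standardGeneric("betweennessCentrality"))

#' @export
setGeneric("localDistance", function(x, ...) standardGeneric("localDistance"))

#' @export
setGeneric("localEfficiency",
           function(x, ...) standardGeneric("localEfficiency"))

#' @export
setGeneric("localAssortativity",
           function(x, ...) standardGeneric("localAssortativity"))

#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @export
setGeneric("selectedNodes", function(x) standardGeneric("selectedNodes"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("performanceMetrics",
           function(x) standardGeneric("performanceMetrics"))

#' @export
setGeneric("foldPredictions", function(x) standardGeneric("foldPredictions"))
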