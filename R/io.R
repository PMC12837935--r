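## Plain-text interchange: per-subject time-series TSV, phenotype CSV,
## edge-list TSV for graphs/connectomes, metric tables and selection
## results. Node indices are 0-based on disk, 1-based in memory.

#' Write / read a subject's time-series matrix
#'
#' TSV with a header row of 0-based node ids; rows are timepoints. The
#' reader tolerates tab- or comma-delimited files.
#'
#' @param ts a [subjectTimeSeries()] or numeric matrix.
#' @param path file path.
#' @return `readTimeSeriesMatrix` returns a numeric matrix.
#' @export
writeTimeSeriesTSV <- function(ts, path) {
  X <- if (is(ts, "SubjectTimeSeries")) tsMatrix(ts) else as.matrix(ts)
  colnames(X) <- sprintf("node_%d", seq_len(ncol(X)) - 1L)
  write.table(X, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeriesTSV
#' @export
readTimeSeriesMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  X <- as.matrix(read.table(path, sep = sep, header = header))
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  X
}

#' Write / read a symmetric weight matrix as an edge list
#'
#' Upper-triangle nonzero entries only, 0-based node indices, columns
#' `node_i`, `node_j`, `weight`.
#'
#' @param W symmetric matrix, a `Connectome`, or a `GroundTruthGraph`.
#' @param path file path.
#' @param nNodes number of nodes (needed to rebuild the matrix).
#' @return `readEdgeList` returns a symmetric matrix.
#' @export
writeEdgeList <- function(W, path) {
  if (is(W, "Connectome")) W <- connectomeMatrix(W)
  if (is(W, "GroundTruthGraph")) W <- adjacencyMatrix(W)
  idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  df <- data.frame(node_i = idx[, 1L] - 1L, node_j = idx[, 2L] - 1L,
                   weight = W[idx])
  df <- df[order(df$node_i, df$node_j), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path, nNodes) {
  df <- read.table(path, sep = "\t", header = TRUE)
  W <- matrix(0, nNodes, nNodes)
  i <- df$node_i + 1L
  j <- df$node_j + 1L
  W[cbind(i, j)] <- df$weight
  W[cbind(j, i)] <- df$weight
  W
}

#' Write a synthetic cohort to disk
#'
#' One `<subject_id>.tsv` time-series file per subject, `phenotype.csv`
#' (subject_id, group, age, sex) and, optionally, per-subject ground-truth
#' edge lists under `graphs/`.
#'
#' @param cohort a [generateCohort()] result.
#' @param dir output directory (created if missing).
#' @param writeGraphs also write ground-truth edge lists.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, writeGraphs = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$timeSeries)
    writeTimeSeriesTSV(ts, file.path(dir, paste0(subjectID(ts), ".tsv")))
  write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"),
            row.names = FALSE, quote = FALSE)
  if (writeGraphs && !is.null(cohort$graphs)) {
    gdir <- file.path(dir, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    for (g in cohort$graphs)
      writeEdgeList(g, file.path(gdir, paste0(subjectID(g), "_graph.tsv")))
  }
  invisible(dir)
}

#' Load a cohort of time-series files with the scan-length filter
#'
#' Reads the phenotype CSV, then one time-series file per listed subject,
#' dropping subjects with fewer than `minTimepoints` rows (the inclusion
#' boundary is inclusive: exactly `minTimepoints` rows are retained). All
#' retained matrices must share the node count; group labels must be among
#' `groupLevels`.
#'
#' @param timeSeriesDir directory holding `<subject_id>.tsv` files.
#' @param phenotypeFile CSV with columns `subject_id` and `group`.
#' @param minTimepoints minimum number of timepoints.
#' @param groupLevels admissible group labels.
#' @return List with `timeSeries` (list of [subjectTimeSeries()]), `labels`
#'   (character) and `excluded` (number of dropped subjects).
#' @export
loadCohort <- function(timeSeriesDir, phenotypeFile, minTimepoints = 140,
                       groupLevels = c("case", "control")) {
  ph <- read.csv(phenotypeFile, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(ph)))
    stop("phenotype file must have subject_id and group columns")
  bad <- setdiff(unique(ph$group), groupLevels)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  tslist <- list()
  labels <- character()
  excluded <- 0L
  nnodes <- NULL
  for (r in seq_len(nrow(ph))) {
    f <- file.path(timeSeriesDir, paste0(ph$subject_id[r], ".tsv"))
    if (!file.exists(f))
      stop("missing time-series file for subject ", ph$subject_id[r])
    X <- readTimeSeriesMatrix(f)
    if (nrow(X) < minTimepoints) { excluded <- excluded + 1L; next }
    if (is.null(nnodes)) nnodes <- ncol(X)
    if (ncol(X) != nnodes)
      stop("node-count mismatch for subject ", ph$subject_id[r],
           " (", ncol(X), " vs ", nnodes, ")")
    tslist[[length(tslist) + 1L]] <-
      subjectTimeSeries(X, ph$subject_id[r], ph$group[r])
    labels <- c(labels, ph$group[r])
  }
  if (!length(tslist))
    stop("no subjects left after the minimum-timepoints filter (",
         excluded, " excluded)")
  if (excluded > 0)
    .msg(excluded, " subject(s) excluded with fewer than ", minTimepoints,
         " timepoints")
  list(timeSeries = tslist, labels = labels, excluded = excluded)
}

#' Write a metric SummarizedExperiment as one TSV per metric
#'
#' Rows are subjects (first column `subject_id`), columns 0-based node ids.
#'
#' @param se the [computeAllMetrics()] result.
#' @param dir output directory.
#' @return Written file paths, invisibly.
#' @export
writeMetricTables <- function(se, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(SummarizedExperiment::assayNames(se), function(m) {
    tab <- metricTable(se, m)
    df <- data.frame(subject_id = rownames(tab), tab, check.names = FALSE)
    p <- file.path(dir, sprintf("metric_%s.tsv", m))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Write a node-selection table as TSV
#'
#' Columns: 0-based `node_id`, `t`, `dof`, `p_raw`, `p_adjusted`,
#' `significant`, `rank`.
#'
#' @param selection a `NodeSelection`.
#' @param path file path.
#' @export
writeSelectionTSV <- function(selection, path) {
  tab <- selectionTable(selection)
  out <- data.frame(node_id = tab$node - 1L,
                    tab[, c("t", "dof", "p_raw", "p_adjusted",
                            "significant", "rank")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export violin-plot data for the top discriminative nodes
#'
#' Long-format table (`subject_id`, `group`, `node_id`, `value`) restricted
#' to the first `topN` selected nodes of `selection`, plus a per-node
#' summary with group means and interquartile ranges, ready for plotting.
#'
#' @param se the [computeAllMetrics()] result.
#' @param selection a `NodeSelection` computed on the same metric.
#' @param labels group labels aligned with subjects.
#' @param topN number of selected nodes to export.
#' @param path optional TSV path; the summary is written alongside with
#'   suffix `_summary.tsv`.
#' @return List with `data` and `summary` data.frames, invisibly when
#'   writing.
#' @export
exportViolinData <- function(se, selection, labels, topN = 5, path = NULL) {
  stopifnot(is(selection, "NodeSelection"))
  tab <- metricTable(se, selection@metric)
  if (ncol(tab) != nrow(selectionTable(selection)))
    stop("selection and metric table have different node counts")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(tab))
  nodes <- head(selectedNodes(selection), topN)
  long <- if (length(nodes)) do.call(rbind, lapply(nodes, function(nd)
    data.frame(subject_id = rownames(tab), group = labels,
               node_id = nd - 1L, value = tab[, nd],
               row.names = NULL)))
  else data.frame(subject_id = character(), group = character(),
                  node_id = integer(), value = numeric())
  summ <- if (length(nodes)) do.call(rbind, lapply(nodes, function(nd)
    do.call(rbind, lapply(unique(labels), function(g) {
      v <- tab[labels == g, nd]
      data.frame(node_id = nd - 1L, group = g, mean = mean(v),
                 q25 = unname(quantile(v, 0.25)),
                 q75 = unname(quantile(v, 0.75)), row.names = NULL)
    }))))
  else data.frame(node_id = integer(), group = character(),
                  mean = numeric(), q25 = numeric(), q75 = numeric())
  if (!is.null(path)) {
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summ, sub("\\.tsv$", "_summary.tsv", path), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(list(data = long, summary = summ)))
  }
  list(data = long, summary = summ)
}
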