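## End-to-end orchestration: load (or point at) a cohort, learn connectomes,
## compute metrics, select nodes, cross-validate, and write every artifact
## plus a manifest with parameters and per-file checksums.

#' Pipeline configuration
#'
#' @param timeSeriesDir directory of `<subject_id>.tsv` time-series files.
#' @param phenotypeFile phenotype CSV (subject_id, group, age, sex).
#' @param outputDir where result artifacts are written.
#' @param graphParams a [graphLearningParams()].
#' @param cv a [cvConfig()].
#' @param q FDR level of the full-sample selection stage.
#' @param minTimepoints scan-length inclusion threshold (subjects with
#'   fewer timepoints are dropped).
#' @param groupLevels admissible group labels; the first is the positive
#'   class.
#' @param topNViolin number of degree-metric nodes exported for violin
#'   plots.
#' @return Classed list.
#' @export
pipelineConfig <- function(timeSeriesDir, phenotypeFile, outputDir,
                           graphParams = graphLearningParams(),
                           cv = cvConfig(), q = 0.05, minTimepoints = 140,
                           groupLevels = c("case", "control"),
                           topNViolin = 5) {
  stopifnot(minTimepoints >= 2)
  structure(list(timeSeriesDir = timeSeriesDir,
                 phenotypeFile = phenotypeFile, outputDir = outputDir,
                 graphParams = graphParams, cv = cv, q = q,
                 minTimepoints = as.integer(minTimepoints),
                 groupLevels = groupLevels,
                 topNViolin = as.integer(topNViolin)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; `graphParams` and
#' `cv` may be given as nested maps overriding individual defaults.
#'
#' @param path YAML file.
#' @return A [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gp <- do.call(graphLearningParams,
                if (is.null(y$graphParams)) list() else y$graphParams)
  cv <- do.call(cvConfig, if (is.null(y$cv)) list() else y$cv)
  args <- y[setdiff(names(y), c("graphParams", "cv"))]
  do.call(pipelineConfig, c(args, list(graphParams = gp, cv = cv)))
}

#' Run the full analysis pipeline
#'
#' Load cohort (with the scan-length filter), learn one sparse connectome
#' per subject, compute the six local metrics, select discriminative nodes
#' per metric on the full sample, evaluate leave-one-out SVM classifiers
#' (per the configured selection mode) and sweep k, exporting:
#' per-subject connectome edge lists, six metric tables, six selection
#' tables with a JSON summary, a per-metric performance table, the k-sweep
#' table, degree-metric violin data, and `manifest.json` with parameters
#' and md5 checksums of every artifact. Deterministic given the config and
#' input files.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`connectomes`,
#'   `metrics`, `selections`, `cvResults`, `sweep`, `manifest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("load_cohort",
    loadCohort(config$timeSeriesDir, config$phenotypeFile,
               config$minTimepoints, config$groupLevels))
  labels <- cohort$labels
  positive <- config$groupLevels[1L]

  connectomes <- stage("build_connectomes", {
    lapply(cohort$timeSeries, function(ts)
      tryCatch(buildConnectome(ts, config$graphParams),
               error = function(e)
                 stop("subject ", subjectID(ts), ": ",
                      conditionMessage(e), call. = FALSE)))
  })
  cdir <- file.path(out, "connectomes")
  dir.create(cdir, showWarnings = FALSE)
  for (cn in connectomes)
    writeEdgeList(cn, file.path(cdir, paste0(subjectID(cn), "_connectome.tsv")))

  se <- stage("compute_metrics", computeAllMetrics(connectomes, labels))
  writeMetricTables(se, file.path(out, "metrics"))

  selections <- stage("select_features", {
    sel <- lapply(metricNames(), function(m)
      suppressWarnings(
        selectFeatures(se, labels, metric = m, k = config$cv$k,
                       q = config$q, requireSignificant = FALSE,
                       positiveClass = positive)))
    names(sel) <- metricNames()
    sel
  })
  sdir <- file.path(out, "selection")
  dir.create(sdir, showWarnings = FALSE)
  for (m in metricNames())
    writeSelectionTSV(selections[[m]],
                      file.path(sdir, sprintf("selection_%s.tsv", m)))
  jsonlite::write_json(
    lapply(selections, function(s)
      list(selected_nodes_0based = selectedNodes(s) - 1L,
           n_significant = sum(selectionTable(s)$significant))),
    file.path(sdir, "selected_nodes.json"), auto_unbox = TRUE)

  cvcfg <- config$cv
  cvcfg$positiveClass <- positive
  cvres <- stage("classification", loocvEvaluate(se, labels, cvcfg))
  perf <- do.call(rbind, lapply(names(cvres), function(m) {
    p <- performanceMetrics(cvres[[m]])
    data.frame(metric = m, accuracy = p["accuracy"],
               sensitivity = p["sensitivity"],
               specificity = p["specificity"], precision = p["precision"],
               f1 = p["f1"], row.names = NULL)
  }))
  write.table(perf, file.path(out, "performance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(cvres, function(r)
      list(confusion = as.list(confusionCounts(r)),
           performance = as.list(performanceMetrics(r)),
           mode = r@mode, k = r@k)),
    file.path(out, "cv_results.json"), auto_unbox = TRUE, digits = NA)

  sweep <- stage("k_sweep", kSweep(se, labels, cvcfg))
  write.table(sweep, file.path(out, "k_sweep.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  stage("violin_export",
    exportViolinData(se, selections$degree, labels,
                     topN = config$topNViolin,
                     path = file.path(out, "violin_degree.tsv")))

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("SparseConnectome")),
    parameters = list(graphParams = unclass(config$graphParams),
                      cv = unclass(cvcfg), q = config$q,
                      minTimepoints = config$minTimepoints,
                      groupLevels = config$groupLevels),
    n_subjects = length(labels),
    n_excluded = cohort$excluded,
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- sub(paste0("^", out, "/?"), "",
                                   names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(connectomes = connectomes, metrics = se,
                 selections = selections, cvResults = cvres, sweep = sweep,
                 manifest = manifest))
}
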