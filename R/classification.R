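## Leave-one-out linear-SVM evaluation on top-k node features, with
## training-fold-only z-scoring and (by default) training-fold-only node
## selection.

#' Cross-validation configuration
#'
#' @param k number of top-ranked nodes fed to the classifier.
#' @param kSweep k values evaluated by [kSweep()].
#' @param selectionMode `"nested"` reselects nodes inside every training
#'   fold (no leakage); `"global"` selects once on the full sample before
#'   cross-validation, replicating the literal select-then-validate
#'   ordering, and is provided to quantify the leakage gap.
#' @param svmCost soft-margin cost C of the linear SVM.
#' @param positiveClass label treated as positive for
#'   sensitivity/precision.
#' @param requireSignificant restrict per-fold selection to FDR-significant
#'   nodes; off by default so that null cohorts (which may have none) can
#'   still be cross-validated on the top-ranked nodes.
#' @param q FDR level used by the selection stage.
#' @param seed reserved; the evaluation path is deterministic.
#' @return Classed list of validated settings.
#' @export
cvConfig <- function(k = 5, kSweep = 1:5,
                     selectionMode = c("nested", "global"),
                     svmCost = 1, positiveClass = "case",
                     requireSignificant = FALSE, q = 0.05, seed = 1) {
  selectionMode <- match.arg(selectionMode)
  stopifnot(k >= 1, all(kSweep >= 1), svmCost > 0, q > 0, q < 1)
  structure(list(k = as.integer(k), kSweep = as.integer(kSweep),
                 selectionMode = selectionMode, svmCost = svmCost,
                 positiveClass = positiveClass,
                 requireSignificant = isTRUE(requireSignificant),
                 q = q, seed = as.integer(seed)),
            class = "CVConfig")
}

#' Fit a z-scoring transform on training data and apply it to both sets
#'
#' Column means and sample standard deviations are computed on the training
#' rows only and applied to training and test rows alike. Zero-variance
#' columns pass through centred only (scale 1).
#'
#' @param train,test numeric matrices with matching columns.
#' @return List with standardized `train` and `test`, plus the fitted
#'   `center` and `scale`.
#' @export
zscoreFitApply <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  stopifnot(nrow(train) >= 2L, ncol(train) == ncol(test))
  ctr <- colMeans(train)
  scl <- apply(train, 2L, sd)
  zero <- !is.finite(scl) | scl == 0
  if (any(zero) && isTRUE(getOption("SparseConnectome.verbose", FALSE)))
    .msg(sum(zero), " zero-variance column(s) passed through centred only",
         level = "warn")
  scl[zero] <- 1
  list(train = sweep(sweep(train, 2L, ctr), 2L, scl, "/"),
       test = sweep(sweep(test, 2L, ctr), 2L, scl, "/"),
       center = ctr, scale = scl)
}

#' Train a linear SVM with uniform class priors
#'
#' Uniform priors are realized as class weights inversely proportional to
#' the class frequencies (`n / (2 n_c)`), so the imbalanced class does not
#' dominate the hinge loss. Deterministic for a fixed input order.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y two-level factor or character vector of labels.
#' @param cost soft-margin cost C.
#' @return A fitted [e1071::svm] object.
#' @export
trainLinearSVM <- function(X, y, cost = 1) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  tab <- table(y)
  cw <- as.numeric(length(y) / (2 * tab))
  names(cw) <- names(tab)
  e1071::svm(x = as.matrix(X), y = y, kernel = "linear", cost = cost,
             class.weights = cw, scale = FALSE)
}

#' Confusion-matrix performance metrics
#'
#' @param TP,FP,TN,FN confusion counts.
#' @return Named vector: accuracy, sensitivity (`TP/(TP+FN)`), specificity
#'   (`TN/(TN+FP)`), precision (`TP/(TP+FP)`) and F1; undefined ratios are
#'   `NA`.
#' @examples
#' confusionMetrics(TP = 67, FP = 9, TN = 89, FN = 7)
#' @export
confusionMetrics <- function(TP, FP, TN, FN) {
  n <- TP + FP + TN + FN
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(TP, TP + FN)
  prec <- div(TP, TP + FP)
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  c(accuracy = div(TP + TN, n), sensitivity = sens,
    specificity = div(TN, TN + FP), precision = prec, f1 = f1)
}

# rank nodes on a training fold: ascending Welch p, ties by index,
# optionally gated on FDR significance
.fold_ranking <- function(X, labels, positiveClass, q, requireSignificant) {
  wt <- suppressWarnings(.welch_columns(X, labels == positiveClass))
  fdr <- bhFDR(wt$p.value, q)
  ord <- order(wt$p.value, seq_along(wt$p.value))
  if (requireSignificant) {
    elig <- ord[fdr$reject[ord]]
    if (length(elig)) ord <- elig
    # with no significant node the full ranking is used (warned upstream)
  }
  ord
}

.loocv_core <- function(X, labels, config, metric, ks = NULL) {
  n <- nrow(X)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  pos <- config$positiveClass
  if (!pos %in% lev) stop("positiveClass '", pos, "' not present in labels")
  if (is.null(ks)) ks <- config$k
  kmax <- max(ks)

  global_rank <- NULL
  if (config$selectionMode == "global")
    global_rank <- .fold_ranking(X, labels, pos, config$q,
                                 config$requireSignificant)

  pred <- matrix(NA_character_, n, length(ks))
  fold_nodes <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    rk <- if (is.null(global_rank))
      .fold_ranking(X[tr, , drop = FALSE], labels[tr], pos, config$q,
                    config$requireSignificant)
    else global_rank
    fold_nodes[[i]] <- rk[seq_len(min(kmax, length(rk)))]
    for (ki in seq_along(ks)) {
      sel <- rk[seq_len(min(ks[ki], length(rk)))]
      zs <- zscoreFitApply(X[tr, sel, drop = FALSE],
                           X[i, sel, drop = FALSE])
      fit <- trainLinearSVM(zs$train, labels[tr], cost = config$svmCost)
      pred[i, ki] <- as.character(predict(fit, zs$test))
    }
  }

  lapply(seq_along(ks), function(ki) {
    p <- pred[, ki]
    TP <- sum(p == pos & labels == pos)
    FP <- sum(p == pos & labels != pos)
    TN <- sum(p != pos & labels != pos)
    FN <- sum(p != pos & labels == pos)
    new("CVResult", metric = metric, mode = config$selectionMode,
        k = as.integer(ks[ki]),
        predictions = data.frame(fold = seq_len(n), true = labels,
                                 predicted = p,
                                 stringsAsFactors = FALSE),
        confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
        performance = confusionMetrics(TP, FP, TN, FN),
        foldNodes = fold_nodes)
  })
}

#' Leave-one-out SVM evaluation per metric
#'
#' For each fold the held-out subject is predicted by a linear SVM trained
#' on the remaining subjects, using the top-k nodes of the fold's ranking
#' (nested mode reranks per fold; global mode uses one full-sample ranking)
#' and a z-scoring transform fitted on the training fold only.
#'
#' @param x the [computeAllMetrics()] result (evaluates every assay) or one
#'   subjects x nodes matrix.
#' @param labels group labels aligned with subjects.
#' @param config a [cvConfig()].
#' @param metric evaluate only this metric when `x` is a
#'   SummarizedExperiment.
#' @return A `CVResult`, or a named list of them (one per metric).
#' @export
loocvEvaluate <- function(x, labels, config = cvConfig(), metric = NULL) {
  if (is(x, "SummarizedExperiment")) {
    metrics <- if (is.null(metric)) SummarizedExperiment::assayNames(x) else
      metric
    out <- lapply(metrics, function(m)
      .loocv_core(metricTable(x, m), labels, config, m)[[1L]])
    names(out) <- metrics
    if (!is.null(metric) && length(metrics) == 1L) return(out[[1L]])
    return(out)
  }
  .loocv_core(as.matrix(x), labels, config,
              if (is.null(metric)) "feature" else metric)[[1L]]
}

#' Accuracy sweep over the number of selected nodes
#'
#' Repeats the leave-one-out evaluation for every `k` in `config$kSweep`
#' (per-fold rankings are computed once and reused across k).
#'
#' @inheritParams loocvEvaluate
#' @return Long data.frame with columns `metric`, `k`, `accuracy`.
#' @export
kSweep <- function(x, labels, config = cvConfig()) {
  metrics <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assayNames(x) else "feature"
  rows <- lapply(metrics, function(m) {
    X <- if (is(x, "SummarizedExperiment")) metricTable(x, m) else
      as.matrix(x)
    res <- .loocv_core(X, labels, config, m, ks = config$kSweep)
    data.frame(metric = m, k = config$kSweep,
               accuracy = vapply(res, function(r)
                 unname(performanceMetrics(r)["accuracy"]), numeric(1)))
  })
  do.call(rbind, rows)
}
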