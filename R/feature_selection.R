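## Node-wise Welch t-tests, Benjamini-Hochberg FDR control, and ascending-p
## top-k node selection.

#' Welch's two-sample t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with sample
#' variances, Welch-Satterthwaite degrees of freedom, and a two-sided
#' p-value from the t distribution. Sign convention: first sample minus
#' second.
#'
#' @param a,b numeric vectors with at least 2 values each; at least one
#'   group must have positive variance.
#' @return List with `statistic`, `dof`, `p.value`.
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 4, 6))
#' @export
welchTTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0)
    stop("both samples have zero variance; t statistic undefined")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, dof = dof, p.value = 2 * pt(-abs(t), dof))
}

# vectorized Welch over the columns of a subjects x nodes matrix;
# zero-variance-in-both columns get t = 0, p = 1 (warned) so a degenerate
# node cannot abort a whole cohort analysis
.welch_columns <- function(X, isA) {
  a <- X[isA, , drop = FALSE]
  b <- X[!isA, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 subjects")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = na))^2) / (na - 1)
  vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1)
  degen <- va == 0 & vb == 0
  se2 <- va / na + vb / nb
  t <- ifelse(degen, 0, (ma - mb) / sqrt(ifelse(degen, 1, se2)))
  dof <- ifelse(degen, NA_real_,
                se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)))
  p <- ifelse(degen, 1, 2 * pt(-abs(t), dof))
  if (any(degen))
    warning(sum(degen), " node(s) constant in both groups; assigned p = 1")
  list(statistic = unname(t), dof = unname(dof), p.value = unname(p))
}

#' Benjamini-Hochberg FDR adjustment and step-up rejections
#'
#' Step-up procedure at level `q`: with sorted p-values `p_(1) <= ... <=
#' p_(m)`, reject hypotheses `1..i*` where `i*` is the largest `i` with
#' `p_(i) <= i q / m`. Adjusted p-values are the standard cumulative-minimum
#' transform; `reject` is equivalent to `adjusted <= q`.
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `adjusted` and logical `reject`.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.5), q = 0.05)$reject
#' @export
bhFDR <- function(p, q = 0.05) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(q > 0, q < 1)
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Rank nodes by ascending p-value and select the top k
#'
#' Ties are broken by lower node index. With `requireSignificant = TRUE`
#' (the default) only FDR-significant nodes are eligible; fewer than `k`
#' eligible nodes triggers a warning and a shorter selection, none at all an
#' error.
#'
#' @param pRaw raw p-values (one per node).
#' @param significant logical FDR-significance flags.
#' @param k number of nodes requested.
#' @param requireSignificant restrict eligibility to significant nodes.
#' @return Integer vector of node indices (1-based), ordered by ascending
#'   p-value.
#' @export
rankAndSelect <- function(pRaw, significant, k,
                          requireSignificant = TRUE) {
  stopifnot(k >= 1, length(pRaw) == length(significant))
  ord <- order(pRaw, seq_along(pRaw))
  eligible <- if (requireSignificant) ord[significant[ord]] else ord
  if (!length(eligible))
    stop("no node is FDR-significant; nothing to select")
  if (length(eligible) < k)
    warning("only ", length(eligible), " eligible node(s) for k = ", k)
  eligible[seq_len(min(k, length(eligible)))]
}

#' Select discriminative nodes for one metric
#'
#' Runs a Welch t-test at every node (case minus control), adjusts the
#' p-values with Benjamini-Hochberg at level `q`, ranks nodes by ascending
#' raw p (ties by index), and selects the top `k`.
#'
#' @param x the [computeAllMetrics()] result (then `metric` is required) or
#'   a subjects x nodes matrix.
#' @param labels group labels aligned with rows/subjects; `positiveClass`
#'   names the group whose mean enters the t statistic with positive sign.
#' @param metric which assay to test when `x` is a SummarizedExperiment.
#' @param k number of nodes to select.
#' @param q FDR level.
#' @param requireSignificant see [rankAndSelect()].
#' @param positiveClass label of the case-like group.
#' @return A `NodeSelection` holding the per-node table (t, dof, raw and
#'   adjusted p, significance flag, rank) and the selected node indices.
#' @export
selectFeatures <- function(x, labels, metric = NULL, k = 5, q = 0.05,
                           requireSignificant = TRUE,
                           positiveClass = "case") {
  X <- if (is(x, "SummarizedExperiment")) {
    if (is.null(metric)) stop("metric must be given for a SummarizedExperiment")
    metricTable(x, metric)
  } else as.matrix(x)
  if (is.null(metric)) metric <- "feature"
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("labels must align with the rows of the metric table")
  if (length(unique(labels)) != 2L) stop("exactly two groups are required")
  if (!positiveClass %in% labels)
    stop("positiveClass '", positiveClass, "' not present in labels")
  isA <- labels == positiveClass
  wt <- .welch_columns(X, isA)
  fdr <- bhFDR(wt$p.value, q)
  n <- ncol(X)
  rk <- integer(n)
  rk[order(wt$p.value, seq_len(n))] <- seq_len(n)
  sel <- rankAndSelect(wt$p.value, fdr$reject, k, requireSignificant)
  tab <- data.frame(node = seq_len(n), t = wt$statistic, dof = wt$dof,
                    p_raw = wt$p.value, p_adjusted = fdr$adjusted,
                    significant = fdr$reject, rank = rk)
  new("NodeSelection", metric = metric, table = tab,
      selected = as.integer(sel), k = as.integer(k), q = q)
}
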