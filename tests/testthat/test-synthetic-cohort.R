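test_that("cohort specifications are validated", {
  expect_error(cohortSpec(nGroupA = 1), "at least 2 subjects")
  expect_error(cohortSpec(plantedNodes = c(1, 1, 2)), "distinct")
  expect_error(cohortSpec(plantedNodes = 60), "1..nNodes")
  expect_error(cohortSpec(smoothingTau = 0), "smoothingTau")
  expect_error(cohortSpec(edgeWeightRange = c(1, 0.5)), "interval")
  expect_silent(cohortSpec(plantedExtraEdges = 0))  # null cohort is legal
})

test_that("planted effect is realized as a degree difference at planted nodes", {
  set.seed(101)
  spec <- cohortSpec(nNodes = 30, nGroupA = 4, nGroupB = 4,
                     plantedNodes = 1:4, plantedExtraEdges = 3,
                     subjectJitter = 0.1, seed = 101)
  template <- makeTemplateGraph(spec)
  nrep <- 200
  degA <- degB <- matrix(0, nrep, spec@nNodes)
  for (r in seq_len(nrep)) {
    gA <- makeGroundTruthGraph(spec, "case", template = template)
    gB <- makeGroundTruthGraph(spec, "control", template = template)
    degA[r, ] <- colSums(adjacencyMatrix(gA) > 0)
    degB[r, ] <- colSums(adjacencyMatrix(gB) > 0)
  }
  diff <- colMeans(degA) - colMeans(degB)
  planted <- spec@plantedNodes
  # planted nodes gain plantedExtraEdges on average (within 10%)
  expect_true(all(abs(diff[planted] - 3) <= 0.3))
  # the added edges land uniformly on the non-planted nodes: their expected
  # gain is (#planted * extra) / (#non-planted), small compared to 3
  expected_spill <- length(planted) * 3 / (spec@nNodes - length(planted))
  expect_lt(max(abs(diff[-planted] - expected_spill)), 0.5)
})

test_that("jitter preserves the degree sequence; no-jitter/no-effect graphs are identical", {
  set.seed(7)
  spec <- cohortSpec(nNodes = 30, nGroupA = 2, nGroupB = 2,
                     subjectJitter = 0.2, plantedExtraEdges = 0)
  template <- makeTemplateGraph(spec)
  g <- makeGroundTruthGraph(spec, "control", template = template)
  expect_equal(sort(colSums(adjacencyMatrix(g) > 0)),
               sort(colSums(template > 0)))
  # total edge count and weight multiset survive the swaps
  expect_equal(sort(adjacencyMatrix(g)[adjacencyMatrix(g) > 0]),
               sort(template[template > 0]))

  spec0 <- cohortSpec(nNodes = 30, nGroupA = 2, nGroupB = 2,
                      subjectJitter = 0, plantedExtraEdges = 0)
  gA <- makeGroundTruthGraph(spec0, "case", template = template)
  gB <- makeGroundTruthGraph(spec0, "control", template = template)
  expect_identical(adjacencyMatrix(gA), adjacencyMatrix(gB))
  expect_identical(adjacencyMatrix(gA), template)
})

test_that("a complete template with no jitter passes through unchanged", {
  spec <- cohortSpec(nNodes = 4, nGroupA = 2, nGroupB = 2,
                     plantedNodes = 1, subjectJitter = 0,
                     plantedExtraEdges = 0)
  tmpl <- complete_graph(4)
  g <- makeGroundTruthGraph(spec, "control", template = tmpl)
  A <- adjacencyMatrix(g)
  expect_equal(sum(A[upper.tri(A)] > 0), 6)  # choose(4, 2)
})

test_that("simulated signals are smooth on the generating graph", {
  set.seed(11)
  spec <- cohortSpec(nNodes = 25, nGroupA = 3, nGroupB = 3, seed = 11)
  template <- makeTemplateGraph(spec)
  dirichlet <- function(X, W) {  # X is T x N, L is N x N
    L <- diag(rowSums(W)) - W
    sum((X %*% L) * X) / sum(X^2)
  }
  for (r in 1:5) {
    g <- makeGroundTruthGraph(spec, "control", template = template)
    W <- adjacencyMatrix(g)
    X <- simulateSmoothSignals(g, 140, smoothingTau = 5, noiseSD = 0.02,
                               targetRMS = 0.3)
    e_true <- dirichlet(X, W)
    wts <- W[upper.tri(W)][W[upper.tri(W)] > 0]
    e_null <- replicate(20, {
      gr <- igraph::rewire(
        igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"),
        igraph::keeping_degseq(niter = 200))
      Ar <- as.matrix(igraph::as_adjacency_matrix(gr))
      Wr <- matrix(0, nrow(W), ncol(W))
      Wr[Ar > 0 & upper.tri(Ar)] <- sample(wts)
      Wr <- Wr + t(Wr)
      dirichlet(X, Wr)
    })
    expect_lt(e_true, median(e_null))
  }
})

test_that("the low-pass filter has the right limits", {
  set.seed(21)
  W <- makeTemplateGraph(cohortSpec(nNodes = 10, nGroupA = 2, nGroupB = 2))
  # tau -> 0: filter approaches the identity, output reproduces the draw
  set.seed(42)
  X <- simulateSmoothSignals(W, 30, smoothingTau = 1e-10, noiseSD = 0)
  set.seed(42)
  E <- matrix(rnorm(10 * 30), 10, 30)
  expect_equal(unname(X), t(E), tolerance = 1e-6)
  # tau large: signals approach graph-constant vectors
  X2 <- simulateSmoothSignals(W, 200, smoothingTau = 1e5, noiseSD = 0)
  across_node_var <- mean(apply(X2, 1, var))
  total_var <- var(as.numeric(X2))
  expect_lt(across_node_var / total_var, 0.01)
})

test_that("signal simulation rejects invalid inputs", {
  W <- path3()
  expect_error(simulateSmoothSignals(W, 10, smoothingTau = 0), "> 0")
  disconnected <- matrix(0, 4, 4)
  disconnected[1, 2] <- disconnected[2, 1] <- 1
  disconnected[3, 4] <- disconnected[4, 3] <- 1
  expect_error(simulateSmoothSignals(disconnected, 10, 1), "connected")
})

test_that("cohort generation is deterministic and has the documented shape", {
  spec <- cohortSpec(nNodes = 15, nGroupA = 3, nGroupB = 4,
                     nTimepoints = 50, plantedNodes = 1:2, seed = 5)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(lapply(a$timeSeries, tsMatrix),
                   lapply(b$timeSeries, tsMatrix))
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(lapply(a$graphs, adjacencyMatrix),
                   lapply(b$graphs, adjacencyMatrix))
  expect_equal(nrow(a$phenotype), 7)
  expect_equal(as.vector(table(a$phenotype$group)[c("case", "control")]),
               c(3, 4))
  expect_true(all(vapply(a$timeSeries, function(ts) nrow(tsMatrix(ts)),
                         integer(1)) == 50))
  # a different seed changes the data
  c2 <- generateCohort(cohortSpec(nNodes = 15, nGroupA = 3, nGroupB = 4,
                                  nTimepoints = 50, plantedNodes = 1:2,
                                  seed = 6))
  expect_false(identical(tsMatrix(a$timeSeries[[1]]),
                         tsMatrix(c2$timeSeries[[1]])))
})

test_that("default spec mirrors the study cohort structure", {
  spec <- cohortSpec()
  expect_equal(spec@nGroupA + spec@nGroupB, 172L)
  expect_equal(spec@nTimepoints, 140L)
  expect_equal(length(spec@plantedNodes), 5L)
})
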