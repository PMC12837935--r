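test_that("pairwise squared distances match hand values and brute force", {
  X <- cbind(c(1, 0), c(0, 1))
  Z <- pairwiseSqDistances(X)
  expect_equal(Z[1, 2], 2)
  expect_equal(diag(Z), c(0, 0))

  X2 <- cbind(a = c(3, 1, 4), b = c(3, 1, 4))  # identical columns
  expect_equal(pairwiseSqDistances(X2)[1, 2], 0)

  set.seed(1)
  X3 <- matrix(rnorm(140 * 5), 140, 5)
  Z3 <- pairwiseSqDistances(X3)
  for (i in 1:5) for (j in 1:5)
    expect_equal(Z3[i, j], sum((X3[, i] - X3[, j])^2), tolerance = 1e-10)

  expect_error(pairwiseSqDistances(cbind(rep(1, 10), rnorm(10)),
                                   standardizeROIs = TRUE), "constant")
})

test_that("the dyad problem matches its closed form", {
  tight <- graphLearningParams(tol = 1e-12)
  W1 <- learnGraphLogDegrees(matrix(c(0, 1, 1, 0), 2, 2), tight)
  expect_equal(W1[1, 2], 0.5, tolerance = 1e-6)
  W0 <- learnGraphLogDegrees(matrix(0, 2, 2), tight)
  expect_equal(W0[1, 2], sqrt(0.5), tolerance = 1e-6)
  # general closed form (-z + sqrt(z^2 + 8*alpha*beta)) / (4*beta)
  for (z in c(0.3, 2, 7)) {
    Wz <- learnGraphLogDegrees(matrix(c(0, z, z, 0), 2, 2), tight)
    expect_equal(Wz[1, 2], (-z + sqrt(z^2 + 8)) / 4, tolerance = 1e-6)
  }
})

test_that("solver matches a generic convex minimizer on small problems", {
  set.seed(2)
  worst <- 0
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    X <- matrix(rnorm(12 * n), 12, n)
    Z <- pairwiseSqDistances(X)
    W <- learnGraphLogDegrees(Z, graphLearningParams(tol = 1e-10))
    mine <- bf_graph_objective(W[upper.tri(W)], Z[upper.tri(Z)], n)
    oracle <- bf_solve_graph(Z)
    worst <- max(worst, abs(mine - oracle) / abs(oracle))
  }
  expect_lt(worst, 1e-4)
})

test_that("post-processing rescales, symmetrizes and prunes in that order", {
  p <- graphLearningParams()  # delta 2, threshold 0.03
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.014   # 0.028 after rescale -> pruned
  W[1, 3] <- W[3, 1] <- 0.5     # 1.0 retained
  cn <- postprocessConnectome(W, p)
  M <- connectomeMatrix(cn)
  expect_equal(M[1, 2], 0)
  expect_equal(M[1, 3], 1)

  # asymmetric input is averaged before pruning
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- 0.4; W2[2, 1] <- 0.2
  cn2 <- postprocessConnectome(W2, graphLearningParams(delta = 1))
  expect_equal(connectomeMatrix(cn2)[1, 2], 0.3)
  expect_equal(connectomeMatrix(cn2)[2, 1], 0.3)

  # negatives are treated as below-threshold
  W3 <- matrix(c(0, -0.2, -0.2, 0), 2, 2)
  expect_equal(connectomeMatrix(postprocessConnectome(W3, p))[1, 2], 0)

  # infinite threshold empties the graph
  Winf <- postprocessConnectome(matrix(runif(16), 4, 4),
                                graphLearningParams(pruneThreshold = Inf))
  expect_true(all(connectomeMatrix(Winf) == 0))
})

test_that("learned connectomes satisfy the structural contract", {
  tc <- tiny_cohort()
  cns <- tiny_connectomes()
  for (cn in cns[1:4]) {
    M <- connectomeMatrix(cn)
    expect_identical(M, t(M))
    expect_equal(diag(M), rep(0, nrow(M)))
    nz <- M[M > 0]
    expect_gte(min(nz), 0.03)
  }
  # pre-pruning degrees are strictly positive (log barrier)
  Z <- pairwiseSqDistances(tc$cohort$timeSeries[[1]])
  W_raw <- learnGraphLogDegrees(Z)
  expect_gt(min(rowSums(W_raw)), 0)
})

test_that("scaling all distances up never increases a learned weight", {
  set.seed(3)
  for (rep in 1:6) {
    X <- matrix(rnorm(30 * 6), 30, 6)
    Z <- pairwiseSqDistances(X) / 10
    p <- graphLearningParams(tol = 1e-10)
    W1 <- learnGraphLogDegrees(Z, p)
    for (cc in c(2, 5)) {
      Wc <- learnGraphLogDegrees(cc * Z, p)
      # slack at the solver's boundary resolution (iterate guard sqrt(tol));
      # meaningful weights are O(0.1)
      expect_true(all(Wc <= W1 + 1e-4))
    }
  }
})

test_that("sparsification is subject-specific and deterministic", {
  tc <- tiny_cohort()
  cns <- tiny_connectomes()
  edge_sets <- lapply(cns[1:4], function(cn) {
    M <- connectomeMatrix(cn)
    which(M[upper.tri(M)] > 0)
  })
  # different subjects yield different edge sets (no shared global threshold)
  expect_gt(length(unique(edge_sets)), 1)
  # identical input -> identical output
  cn_a <- buildConnectome(tc$cohort$timeSeries[[1]])
  cn_b <- buildConnectome(tc$cohort$timeSeries[[1]])
  expect_identical(connectomeMatrix(cn_a), connectomeMatrix(cn_b))
})

test_that("graph learning recovers planted structure better than thresholded correlation", {
  set.seed(31)
  f1_score <- function(est, truth) {
    e <- est[upper.tri(est)] > 0
    t <- truth[upper.tri(truth)] > 0
    tp <- sum(e & t)
    if (tp == 0) return(0)
    pr <- tp / sum(e); rc <- tp / sum(t)
    2 * pr * rc / (pr + rc)
  }
  spec <- cohortSpec(nNodes = 20, nGroupA = 2, nGroupB = 2,
                     plantedExtraEdges = 0)
  wins <- 0L
  nseeds <- 50L
  for (s in seq_len(nseeds)) {
    tmpl <- makeTemplateGraph(spec)
    X <- simulateSmoothSignals(tmpl, 140, smoothingTau = 5, noiseSD = 0.02,
                               targetRMS = 0.3)
    W <- connectomeMatrix(buildConnectome(X))
    ne <- sum(W[upper.tri(W)] > 0)
    C <- abs(cor(X)); diag(C) <- 0
    cut <- sort(C[upper.tri(C)], decreasing = TRUE)[max(ne, 1)]
    Ac <- (C >= cut) * 1; diag(Ac) <- 0
    if (f1_score(W, tmpl) > f1_score(Ac, tmpl)) wins <- wins + 1L
  }
  expect_gte(wins / nseeds, 0.7)
})
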