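test_that("z-scoring is fitted on the training rows only", {
  z <- zscoreFitApply(matrix(c(1, 2, 3), 3, 1), matrix(2, 1, 1))
  expect_equal(as.numeric(z$train), c(-1, 0, 1))
  expect_equal(as.numeric(z$test), 0)  # test value at the train mean

  # the fitted transform is not idempotent
  z2 <- sweep(sweep(z$train, 2, z$center), 2, z$scale, "/")
  expect_false(isTRUE(all.equal(as.numeric(z2), as.numeric(z$train))))

  # zero-variance columns pass through centred
  zc <- zscoreFitApply(matrix(c(2, 2, 2, 1, 2, 3), 3, 2),
                       matrix(c(2, 5), 1, 2))
  expect_equal(as.numeric(zc$train[, 1]), c(0, 0, 0))
})

test_that("the linear SVM separates, respects symmetry and class weights", {
  X <- matrix(c(-3, -2.5, -2, 2, 2.5, 3), 6, 1)
  y <- rep(c("case", "control"), each = 3)
  fit <- trainLinearSVM(X, y)
  expect_equal(as.character(predict(fit, X)), y)

  # flipping labels flips every prediction
  fit2 <- trainLinearSVM(X, rev(y))
  expect_equal(as.character(predict(fit2, X)), rev(y))

  # imbalanced but separable: the weighted fit still classifies the
  # minority class correctly
  set.seed(14)
  Xi <- matrix(c(rnorm(4, -4, 0.3), rnorm(40, 4, 0.3)), ncol = 1)
  yi <- rep(c("case", "control"), c(4, 40))
  fiti <- trainLinearSVM(Xi, yi)
  expect_equal(as.character(predict(fiti, Xi)), yi)
  # and the boundary sits in the margin gap, not next to the minority blob
  mid <- predict(fiti, matrix(c(-1, 1), 2, 1))
  expect_equal(as.character(mid), c("case", "control"))

  expect_error(trainLinearSVM(X, rep("case", 6)), "single class")
})

test_that("confusion metrics reproduce their definitions", {
  m <- confusionMetrics(TP = 67, FP = 9, TN = 89, FN = 7)
  expect_equal(unname(m["accuracy"]), 0.907, tolerance = 5e-4)
  expect_equal(unname(m["sensitivity"]), 0.905, tolerance = 5e-4)
  expect_equal(unname(m["specificity"]), 0.908, tolerance = 5e-4)
  expect_equal(unname(m["precision"]), 0.882, tolerance = 5e-4)
  expect_equal(unname(m["f1"]), 0.893, tolerance = 5e-4)
  # identities
  expect_equal(unname(m["accuracy"]) * 172, 67 + 89, tolerance = 1e-12)
  expect_equal(unname(m["f1"]),
               2 * m[["precision"]] * m[["sensitivity"]] /
                 (m[["precision"]] + m[["sensitivity"]]),
               tolerance = 1e-12)
})

test_that("LOOCV is perfect on a perfectly separating feature", {
  set.seed(15)
  n <- 30
  labels <- rep(c("case", "control"), c(14, 16))
  X <- cbind(ifelse(labels == "case", 1, -1) + rnorm(n, sd = 0.05),
             matrix(rnorm(n * 4), n, 4))
  cv <- loocvEvaluate(X, labels, cvConfig(k = 1))
  expect_equal(unname(performanceMetrics(cv)["accuracy"]), 1)
  expect_equal(sum(confusionCounts(cv)), n)
})

test_that("LOOCV confusion counts are invariant to subject order", {
  set.seed(16)
  n <- 24
  labels <- rep(c("case", "control"), each = 12)
  X <- matrix(rnorm(n * 6), n, 6)
  X[labels == "case", 2] <- X[labels == "case", 2] + 1.5
  cv1 <- loocvEvaluate(X, labels, cvConfig(k = 2))
  perm <- sample(n)
  cv2 <- loocvEvaluate(X[perm, ], labels[perm], cvConfig(k = 2))
  expect_equal(confusionCounts(cv1), confusionCounts(cv2))
})

test_that("nested selection stays at chance on noise while global selection leaks", {
  set.seed(17)
  reps <- 4
  acc <- matrix(NA_real_, reps, 2,
                dimnames = list(NULL, c("nested", "global")))
  for (r in seq_len(reps)) {
    n <- 40
    labels <- rep(c("case", "control"), each = 20)
    X <- matrix(rnorm(n * 30), n, 30)
    for (mode in colnames(acc)) {
      cv <- loocvEvaluate(X, labels,
                          cvConfig(k = 3, selectionMode = mode))
      acc[r, mode] <- performanceMetrics(cv)["accuracy"]
    }
  }
  # global (whole-sample) selection systematically beats nested on noise --
  # that optimism is exactly the leakage the nested default avoids
  expect_gt(mean(acc[, "global"]), mean(acc[, "nested"]))
  # nested stays within binomial noise of chance
  expect_lt(mean(acc[, "nested"]), 0.5 + 1.96 * sqrt(0.25 / (reps * 40)))
})

test_that("the k sweep reuses rankings and handles scarce significant nodes", {
  set.seed(18)
  n <- 26
  labels <- rep(c("case", "control"), each = 13)
  X <- matrix(rnorm(n * 8), n, 8)
  X[labels == "case", 5] <- X[labels == "case", 5] + 3
  sw <- kSweep(X, labels, cvConfig(kSweep = 1:3))
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))

  # requireSignificant with a single strong node: k beyond the eligible set
  # falls back to the eligible nodes only
  cv <- loocvEvaluate(X, labels,
                      cvConfig(k = 4, requireSignificant = TRUE))
  kused <- vapply(cv@foldNodes, length, integer(1))
  expect_true(all(kused >= 1))
  expect_gt(unname(performanceMetrics(cv)["accuracy"]), 0.8)
})

test_that("per-metric evaluation runs off the metric container", {
  cns <- tiny_connectomes()
  labels <- tiny_cohort()$cohort$phenotype$group
  se <- computeAllMetrics(cns, labels)
  res <- loocvEvaluate(se, labels, cvConfig(k = 2))
  expect_setequal(names(res), metricNames())
  for (r in res) expect_equal(sum(confusionCounts(r)), length(labels))
})
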