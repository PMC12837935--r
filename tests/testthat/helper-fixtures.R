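# Small named graphs used across metric tests (unit weights unless noted),
# and a lazily built miniature cohort shared by the io/pipeline tests.

path3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  W
}

complete_graph <- function(n, w = 1) {
  W <- matrix(w, n, n)
  diag(W) <- 0
  W
}

star_graph <- function(n) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  W
}

cycle_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    W[i, j] <- W[j, i] <- 1
  }
  W
}

.fixture_env <- new.env(parent = emptyenv())

# 20-node, 6 + 8 subject cohort; built once per test run
tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    spec <- cohortSpec(nNodes = 20, nGroupA = 6, nGroupB = 8,
                       nTimepoints = 140, plantedNodes = 1:3,
                       plantedExtraEdges = 3, seed = 99)
    .fixture_env$tiny <- list(spec = spec, cohort = generateCohort(spec))
  }
  .fixture_env$tiny
}

tiny_connectomes <- function() {
  if (is.null(.fixture_env$tiny_cns)) {
    tc <- tiny_cohort()
    .fixture_env$tiny_cns <- buildConnectomes(tc$cohort$timeSeries)
  }
  .fixture_env$tiny_cns
}
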