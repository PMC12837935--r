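# Brute-force oracles used to validate the fast implementations. These are
# deliberately naive (exhaustive enumeration, generic optimizers) and share
# no code with the package internals.

# random symmetric nonnegative zero-diagonal weight matrix
rand_weighted_graph <- function(n, p_edge = 0.5, wmin = 0.2, wmax = 1.5) {
  W <- matrix(0, n, n)
  iu <- which(upper.tri(W))
  on <- runif(length(iu)) < p_edge
  W[iu[on]] <- runif(sum(on), wmin, wmax)
  W + t(W)
}

# --- shortest paths ---------------------------------------------------------

# Floyd-Warshall on edge lengths 1/W (0 weight = no edge)
bf_shortest_paths <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# all simple paths i -> j by depth-first enumeration; returns list of node
# sequences
bf_all_simple_paths <- function(W, from, to) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (u in which(W[v, ] > 0))
      if (!u %in% path) walk(c(path, u))
  }
  walk(from)
  out
}

# --- node metrics -----------------------------------------------------------

bf_degree <- function(W) colSums(W > 0)

bf_clustering <- function(W) {
  A <- W > 0
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  })
}

bf_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  B <- numeric(n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    paths <- bf_all_simple_paths(W, j, k)
    if (!length(paths)) next
    lens <- vapply(paths, function(p)
      sum(1 / W[cbind(p[-length(p)], p[-1])]), numeric(1))
    best <- min(lens)
    short <- paths[lens <= best + tol]
    sigma <- length(short)
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      through <- sum(vapply(short, function(p) i %in% p, logical(1)))
      B[i] <- B[i] + through / sigma
    }
  }
  B
}

bf_distance <- function(W) {
  D <- bf_shortest_paths(W)
  diag(D) <- NA
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    d <- D[i, ]
    d <- d[!is.na(d) & is.finite(d)]
    if (!length(d)) 0 else mean(d)
  })
}

bf_efficiency <- function(W) {
  A <- W > 0
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    D <- bf_shortest_paths(W[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (k * (k - 1))
  })
}

# Newman's global degree assortativity from the stub (excess-degree) joint
# distribution; NA when the stub variance vanishes
bf_global_assortativity <- function(W) {
  A <- W > 0
  K <- colSums(A)
  el <- which(A & upper.tri(A), arr.ind = TRUE)
  M <- nrow(el)
  q <- c(K[el[, 1]] - 1, K[el[, 2]] - 1)        # one entry per stub
  mu <- mean(q)
  s2 <- mean(q^2) - mu^2
  if (s2 <= 1e-12) return(NA_real_)
  jk <- mean((K[el[, 1]] - 1) * (K[el[, 2]] - 1))
  (jk - mu^2) / s2
}

# --- statistics -------------------------------------------------------------

# definitional BH step-up: check every threshold i*q/m
bf_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  istar <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) istar <- i
  reject <- logical(m)
  if (istar > 0) reject[ord[seq_len(istar)]] <- TRUE
  reject
}

bf_bh_adjust <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# --- graph-learning objective ----------------------------------------------

# full objective on the upper-triangle weight vector
bf_graph_objective <- function(w, z, n, alpha = 1, beta = 1) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- numeric(n)
  for (e in seq_along(w)) {
    d[ut[e, 1]] <- d[ut[e, 1]] + w[e]
    d[ut[e, 2]] <- d[ut[e, 2]] + w[e]
  }
  if (any(d <= 0)) return(1e10)
  2 * sum(z * w) - alpha * sum(log(d)) + 2 * beta * sum(w^2)
}

# generic constrained convex minimization with multiple restarts
bf_solve_graph <- function(Z, alpha = 1, beta = 1, starts = 5) {
  n <- nrow(Z)
  z <- Z[upper.tri(Z)]
  best <- Inf
  for (s in seq_len(starts)) {
    w0 <- runif(length(z), 0.05, 1)
    o <- optim(w0, bf_graph_objective, z = z, n = n, alpha = alpha,
               beta = beta, method = "L-BFGS-B", lower = 1e-12,
               control = list(maxit = 5000, factr = 1e3))
    if (o$value < best) best <- o$value
  }
  best
}
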