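# Brute-force reference implementations used to validate the graph
# metrics. These are deliberately naive and independent of the package
# internals (no igraph, no compiled code): Floyd-Warshall distances,
# explicit triangle counting, and shortest-path counting via adjacency
# matrix powers.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  Ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]] > 0) links <- links + 1
    Ci[i] <- links / (k * (k - 1) / 2)
  }
  list(node = Ci, global = mean(Ci))
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin)) return(NaN)
  mean(off[fin])
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    e[i] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(e)
}

# Betweenness by explicit shortest-path counting: the number of geodesics
# from s to t equals the (s,t) entry of A^d at d = d(s,t), and the number
# through v is the product of the two leg counts when the legs add up.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  maxd <- max(D[is.finite(D)], 1)
  pow <- vector("list", maxd)
  pow[[1]] <- A
  if (maxd > 1)
    for (d in 2:maxd) pow[[d]] <- pow[[d - 1]] %*% A
  sigma <- function(i, j) {
    d <- D[i, j]
    if (!is.finite(d) || d == 0) return(0)
    pow[[d]][i, j]
  }
  B <- numeric(n)
  for (s in seq_len(n - 1))
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      n_st <- sigma(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t])
          B[v] <- B[v] + sigma(s, v) * sigma(v, t) / n_st
      }
    }
  B
}

oracle_largest_component <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  best <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nxt <- setdiff(which(colSums(A[frontier, , drop = FALSE] > 0) > 0),
                     which(seen))
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    best <- max(best, length(comp))
  }
  best
}

# Random undirected graph / correlation-matrix generators for property tests.
rand_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

rand_corr <- function(n) {
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- runif(n * (n - 1) / 2, -0.99, 0.99)
  C <- C + t(C)
  dimnames(C) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  C
}

# binary_graph object from a raw adjacency matrix (white-box constructor
# for metric tests; sparsity/threshold are not meaningful here).
bg <- function(A) {
  storage.mode(A) <- "logical"
  diag(A) <- FALSE
  if (is.null(colnames(A)))
    dimnames(A) <- list(sprintf("n%02d", seq_len(nrow(A))),
                        sprintf("n%02d", seq_len(nrow(A))))
  structure(list(adjacency = A, sparsity = NA_real_, threshold = NA_real_,
                 n_edges = sum(A) / 2, target_edges = NA_integer_),
            class = "binary_graph")
}

# complete-graph binary_graph on n nodes
bg_complete <- function(n) {
  A <- matrix(TRUE, n, n)
  bg(A)
}
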