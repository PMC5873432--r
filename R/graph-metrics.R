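#' Sparsity grid
#'
#' The ordered set of sparsity degrees at which correlation matrices are
#' binarized. A sparsity of 0.9 discards the weakest 90% of `|r|` values
#' and keeps the top 10%. The default grid 0.5 to 0.9 in steps of 0.02
#' (21 points) spans the range in which covariance-network attributes are
#' conventionally estimated.
#'
#' @param lo,hi,step grid specification, all in `[0, 1)`.
#' @return Strictly increasing numeric vector.
#' @export
sparsity_grid <- function(lo = 0.5, hi = 0.9, step = 0.02) {
  stopifnot(lo >= 0, hi < 1, lo <= hi, step > 0)
  g <- seq(lo, hi, by = step)
  validate_sparsity_grid(g)
  g
}

validate_sparsity_grid <- function(g) {
  stopifnot(is.numeric(g), length(g) >= 1, all(g >= 0), all(g < 1))
  if (length(g) > 1 && is.unsorted(g, strictly = TRUE))
    stop("sparsity grid must be strictly increasing")
  invisible(g)
}

#' Threshold a correlation matrix into a binary graph
#'
#' Binarizes at the given sparsity: the threshold `Rk` is the order
#' statistic of the off-diagonal `|Cij|` values such that a fraction
#' `1 - sparsity` of pairs satisfies `|Cij| > Rk` (strict retention of the
#' upper tail, sign ignored). With distinct `|Cij|` the edge count equals
#' `round((1 - sparsity) * N(N-1)/2)` exactly; ties at `Rk` make the
#' realized count undershoot the target, which is recorded in the result.
#'
#' @param corr correlation matrix.
#' @param sparsity sparsity degree in `[0, 1)`.
#' @return A `binary_graph`: `adjacency` (logical, symmetric, false
#'   diagonal), `sparsity`, `threshold`, `n_edges`, `target_edges`.
#' @export
threshold_at_sparsity <- function(corr, sparsity) {
  validate_correlation_matrix(corr)
  if (nrow(corr) < 2) stop("need at least 2 regions")
  stopifnot(sparsity >= 0, sparsity < 1)
  absv <- abs(corr[upper.tri(corr)])
  make_binary_graph(corr, sort(absv, decreasing = TRUE), sparsity)
}

# Shared kernel: `sorted` is the descending |Cij| vector (length N(N-1)/2).
make_binary_graph <- function(corr, sorted, sparsity) {
  P <- length(sorted)
  k <- round((1 - sparsity) * P)
  if (k > 0 && sorted[1] == sorted[P])
    stop("tie-degenerate matrix: all |Cij| equal, target sparsity unattainable")
  Rk <- if (k >= P) 0 else sorted[k + 1]
  A <- abs(corr) > Rk
  diag(A) <- FALSE
  n_edges <- sum(A) / 2
  structure(list(
    adjacency = A,
    sparsity = sparsity,
    threshold = Rk,
    n_edges = n_edges,
    target_edges = k
  ), class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat("Binary graph:", nrow(x$adjacency), "nodes,", x$n_edges,
      "edges (sparsity", x$sparsity, ", Rk =", signif(x$threshold, 4), ")\n")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Clustering index
#'
#' Per-node clustering: the number of existing links among a node's
#' neighbors divided by the number possible; 0 for nodes of degree < 2.
#' The graph-level index C is the mean over all N nodes and equals 1 if
#' and only if the graph is complete.
#'
#' @param graph a `binary_graph`.
#' @return List with `node` (per-node Ci) and `global` (C).
#' @export
clustering_index <- function(graph) {
  A <- graph$adjacency * 1
  deg <- rowSums(A)
  tri <- rowSums(A * (A %*% A))       # 2 x triangles through each node
  Ci <- ifelse(deg < 2, 0, tri / (deg * (deg - 1)))
  list(node = setNames(Ci, colnames(A)), global = mean(Ci))
}

#' Characteristic path length
#'
#' Mean geodesic (shortest-path) distance over ordered pairs of distinct
#' nodes. Disconnected pairs have no finite geodesic; they are excluded
#' from the mean and their fraction reported, the usual convention for
#' covariance networks that fragment at high sparsity. With no connected
#' pair at all, `L` is `NaN` and `defined` is `FALSE`.
#'
#' @param graph a `binary_graph`.
#' @return List: `L`, `disconnected_fraction`, `defined`.
#' @export
path_length <- function(graph) {
  D <- igraph::distances(as_igraph(graph))
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  if (!any(fin))
    return(list(L = NaN, disconnected_fraction = 1, defined = FALSE))
  list(L = mean(off[fin]), disconnected_fraction = mean(!fin), defined = TRUE)
}

#' Global efficiency
#'
#' Mean inverse geodesic distance over all ordered pairs of distinct
#' nodes, with disconnected pairs contributing 0. Equals 1 for a complete
#' graph and 0 for an edgeless one.
#'
#' @param graph a `binary_graph`.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(graph) {
  n <- nrow(graph$adjacency)
  if (n < 2) return(0)
  D <- igraph::distances(as_igraph(graph))
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For every node, the global efficiency of the subgraph induced by its
#' neighbors (the node itself excluded); nodes of degree < 2 contribute
#' 0. The graph-level index is the mean over all N nodes. It measures
#' fault tolerance: how efficiently a node's neighborhood communicates
#' once the node is removed.
#'
#' @param graph a `binary_graph`.
#' @return Scalar in `[0, 1]`, with per-node values as attribute `node`.
#' @export
local_efficiency <- function(graph) {
  node <- local_efficiency_nodes_cpp(graph$adjacency)
  structure(mean(node), node = setNames(node, colnames(graph$adjacency)))
}

#' Betweenness centrality and its normalization
#'
#' Node betweenness `Bi` counts the shortest paths between all other node
#' pairs that pass through the node, fractionally over equal-length
#' alternatives (Freeman/Brandes definition). The normalized value
#' `bi = Bi / <B>` divides by the network mean; when every `Bi` is 0
#' (e.g. a complete graph) all `bi` are defined as 0 and flagged.
#'
#' @param graph a `binary_graph`.
#' @return `data.frame` with `region_id`, `degree`, `betweenness`, `nbc`;
#'   attributes `mean_betweenness` and `zero_flag`.
#' @export
betweenness_centrality <- function(graph) {
  B <- igraph::betweenness(as_igraph(graph), directed = FALSE)
  meanB <- mean(B)
  zero <- meanB == 0
  nbc <- if (zero) rep(0, length(B)) else B / meanB
  structure(
    data.frame(region_id = colnames(graph$adjacency) %||% seq_along(B),
               degree = rowSums(graph$adjacency),
               betweenness = unname(B),
               nbc = unname(nbc),
               stringsAsFactors = FALSE, row.names = NULL),
    mean_betweenness = meanB, zero_flag = zero
  )
}

#' Per-node metrics of a binary graph
#'
#' Combines degree, clustering, betweenness and normalized betweenness.
#'
#' @param graph a `binary_graph`.
#' @return `data.frame`, one row per region, with attributes of
#'   [betweenness_centrality()].
#' @export
node_metrics <- function(graph) {
  bc <- betweenness_centrality(graph)
  bc$clustering <- unname(clustering_index(graph)$node)
  structure(bc, mean_betweenness = attr(bc, "mean_betweenness"),
            zero_flag = attr(bc, "zero_flag"))
}

#' Identify network hubs
#'
#' Hubs are the nodes whose normalized betweenness centrality strictly
#' exceeds the threshold (default 1.5), sorted by NBC descending.
#'
#' @param metrics output of [betweenness_centrality()] or [node_metrics()].
#' @param threshold NBC cutoff.
#' @return `data.frame` of hub rows, NBC-descending.
#' @export
identify_hubs <- function(metrics, threshold = 1.5) {
  stopifnot(is.data.frame(metrics), "nbc" %in% names(metrics))
  hubs <- metrics[metrics$nbc > threshold, , drop = FALSE]
  hubs[order(-hubs$nbc, hubs$region_id), , drop = FALSE]
}

#' All global metrics of one binary graph
#'
#' @param graph a `binary_graph`.
#' @return List: `C`, `L`, `Eglob`, `Eloc`, `largest_component_fraction`,
#'   `disconnected_pair_fraction`.
#' @export
graph_metrics <- function(graph) {
  graph_summary(graph)[c("C", "L", "Eglob", "Eloc",
                         "largest_component_fraction",
                         "disconnected_pair_fraction")]
}

# One pass over a binary graph: igraph object and BFS distance matrix are
# built once and every derived quantity read off them.
graph_summary <- function(graph, betweenness = FALSE, attack = FALSE) {
  A <- graph$adjacency
  n <- nrow(A)
  ig <- as_igraph(graph)
  D <- igraph::distances(ig)
  off <- D[row(D) != col(D)]
  fin <- is.finite(off)
  L <- if (any(fin)) mean(off[fin]) else NaN
  inv <- 1 / off
  inv[!fin] <- 0
  Eglob <- if (n >= 2) mean(inv) else 0
  comp <- max(igraph::components(ig)$csize) / n
  out <- list(
    C = clustering_index(graph)$global,
    L = L,
    Eglob = Eglob,
    Eloc = mean(local_efficiency_nodes_cpp(A)),
    largest_component_fraction = comp,
    disconnected_pair_fraction = mean(!fin)
  )
  if (betweenness || attack) {
    B <- igraph::betweenness(ig, directed = FALSE)
    meanB <- mean(B)
    out$nbc <- if (meanB == 0) rep(0, n) else unname(B / meanB)
    out$mean_betweenness <- meanB
  }
  if (attack) {
    ids <- colnames(A) %||% as.character(seq_len(n))
    ord <- order(-out$nbc, -rowSums(A), ids)
    lcc <- attack_lcc_cpp(A, as.integer(ord - 1L))
    out$robustness_auc <- auc_trapezoid((0:n) / n, lcc / n)
  }
  out
}

#' Network-attribute curves over the sparsity grid
#'
#' Thresholds the correlation matrix at every sparsity of the grid and
#' samples the clustering index, characteristic path length, global and
#' local efficiency; each curve carries its trapezoid area under the
#' curve (AUC), the scalar used for group comparison.
#'
#' @param corr correlation matrix.
#' @param grid sparsity grid from [sparsity_grid()].
#' @return Named list of `property_curve` objects
#'   (`C`, `L`, `Eglob`, `Eloc`), each with fields `property`,
#'   `sparsity`, `values`, `auc`.
#' @export
property_curves <- function(corr, grid = sparsity_grid()) {
  validate_sparsity_grid(grid)
  graphs <- threshold_series(corr, grid)
  vals <- vapply(graphs, function(g) {
    gm <- graph_metrics(g)
    c(C = gm$C, L = gm$L, Eglob = gm$Eglob, Eloc = gm$Eloc)
  }, numeric(4))
  lapply(setNames(rownames(vals), rownames(vals)), function(p)
    property_curve(p, grid, vals[p, ]))
}

property_curve <- function(property, sparsity, values) {
  auc <- if (all(is.finite(values))) {
    if (length(sparsity) < 2) suppressWarnings(auc_trapezoid(sparsity, values))
    else auc_trapezoid(sparsity, values)
  } else NA_real_
  structure(list(property = property, sparsity = sparsity,
                 values = unname(values), auc = auc),
            class = "property_curve")
}

# Threshold once per grid point, sorting |Cij| a single time.
threshold_series <- function(corr, grid) {
  validate_correlation_matrix(corr)
  sorted <- sort(abs(corr[upper.tri(corr)]), decreasing = TRUE)
  lapply(grid, function(s) make_binary_graph(corr, sorted, s))
}

#' Scalar network statistics of one correlation matrix
#'
#' The workhorse evaluated on every bootstrap resample and every sliding
#' window: AUCs of the four global attributes over the sparsity grid, the
#' targeted-attack robustness AUC, connectivity summaries (global,
#' homologous, per lobe), and optionally the per-region NBC AUC.
#'
#' @param corr correlation matrix.
#' @param regions aligned region table.
#' @param grid sparsity grid.
#' @param include character subset of
#'   `c("auc", "robustness", "connectivity", "nbc")`.
#' @return Named numeric vector.
#' @export
network_statistics <- function(corr, regions, grid = sparsity_grid(),
                               include = c("auc", "robustness", "connectivity")) {
  validate_sparsity_grid(grid)
  out <- numeric(0)
  need_graphs <- any(c("auc", "robustness", "nbc") %in% include)
  if (need_graphs) {
    graphs <- threshold_series(corr, grid)
    summaries <- lapply(graphs, graph_summary,
                        betweenness = "nbc" %in% include,
                        attack = "robustness" %in% include)
  }
  if ("auc" %in% include) {
    vals <- vapply(summaries, function(s) c(s$C, s$L, s$Eglob, s$Eloc), numeric(4))
    out <- c(out,
             auc_clustering = auc_trapezoid(grid, vals[1, ]),
             auc_path_length = auc_trapezoid(grid, vals[2, ]),
             auc_global_efficiency = auc_trapezoid(grid, vals[3, ]),
             auc_local_efficiency = auc_trapezoid(grid, vals[4, ]))
  }
  if ("robustness" %in% include) {
    rob <- vapply(summaries, `[[`, numeric(1), "robustness_auc")
    out <- c(out, auc_robustness = auc_trapezoid(grid, rob))
  }
  if ("connectivity" %in% include) {
    out <- c(out,
             conn_global = connectivity_summary(corr, regions, "global")$mean_abs_corr,
             conn_homologous = if (nrow(homologous_pairs(regions)))
               connectivity_summary(corr, regions, "homologous")$mean_abs_corr
             else NA_real_)
    for (lobe in intersect(.lobes, regions$lobe[duplicated(regions$lobe) |
                                                  duplicated(regions$lobe, fromLast = TRUE)])) {
      cs <- connectivity_summary(corr, regions, paste0("lobe:", lobe))
      out[paste0("conn_lobe_", lobe)] <- cs$mean_abs_corr
    }
  }
  if ("nbc" %in% include) {
    nbc <- vapply(summaries, `[[`, numeric(nrow(corr)), "nbc")
    nbc_auc <- apply(nbc, 1, function(v) auc_trapezoid(grid, v))
    names(nbc_auc) <- paste0("nbc_auc_", regions$region_id)
    out <- c(out, nbc_auc)
  }
  out
}
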