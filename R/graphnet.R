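# Graph construction and network properties: threshold binarization,
# clustering coefficient, characteristic path length, node degree.

#' Binarize a connectivity matrix at a fraction of its maximum
#'
#' An edge is drawn between channels p and q (p != q) when their PLV
#' strictly exceeds `fraction` times the maximum off-diagonal PLV. The
#' diagonal (self-PLV, identically 1) is excluded from the maximum:
#' including it would fix the cut at `fraction` regardless of the data. Set
#' `diagonal = "include"` for the alternative fixed-cut reading.
#'
#' @param matrix A `connectivity_matrix` from [plv_matrix()], or a plain
#'   symmetric numeric matrix.
#' @param fraction Proportion of the maximum used as the cut, in `(0, 1]`
#'   (default 0.8).
#' @param diagonal `"exclude"` (default) or `"include"`: whether the
#'   diagonal participates in the maximum.
#' @return An object of class `binary_graph`: list with `adjacency`
#'   (logical matrix, FALSE diagonal), `channel_labels`, `threshold_used`
#'   (the absolute cut) and `source` provenance.
#' @examples
#' m <- matrix(c(1, .9, .2, .9, 1, .73, .2, .73, 1), 3,
#'             dimnames = rep(list(c("a", "b", "c")), 2))
#' binarize(m)$adjacency
#' @export
binarize <- function(matrix, fraction = 0.8,
                     diagonal = c("exclude", "include")) {
  diagonal <- match.arg(diagonal)
  if (inherits(matrix, "connectivity_matrix")) {
    V <- matrix$values
    src <- list(subject_id = matrix$subject_id, condition = matrix$condition,
                band = if (is.null(matrix$band)) NULL else matrix$band$name,
                group = matrix$group)
  } else {
    V <- as.matrix(matrix)
    src <- list()
  }
  if (!is_number(fraction) || fraction <= 0 || fraction > 1)
    plv_stop("invalid_input", "fraction must lie in (0, 1]")
  if (nrow(V) != ncol(V) || max(abs(V - t(V))) > 1e-9)
    plv_stop("invalid_input", "connectivity matrix must be square symmetric")
  labels <- rownames(V) %||% as.character(seq_len(nrow(V)))
  off <- V
  if (diagonal == "exclude") diag(off) <- -Inf
  mx <- max(off)
  if (mx <= 0) {
    plv_warn("empty_graph", "all off-diagonal entries are <= 0; empty graph")
    adj <- matrix(FALSE, nrow(V), ncol(V))
    cut <- 0
  } else {
    cut <- fraction * mx
    adj <- V > cut            # strict: ties at the cut are not edges
    diag(adj) <- FALSE
    if (!any(adj))
      plv_warn("empty_graph", "no entry exceeds the cut %.4g; empty graph", cut)
  }
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, channel_labels = labels,
                 threshold_used = cut, fraction = fraction, source = src),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph: %d nodes, %d edges, cut = %.4g>\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$threshold_used))
  invisible(x)
}

as_adjacency <- function(graph) {
  if (inherits(graph, "binary_graph")) graph$adjacency
  else {
    a <- as.matrix(graph) != 0
    diag(a) <- FALSE
    a
  }
}

#' Clustering coefficient
#'
#' Per node, `CC_i = 2 t_i / (k_i (k_i - 1))` where `k_i` is the node's
#' degree and `t_i` the number of edges among its neighbours (triangles
#' through i). Nodes with fewer than two neighbours get `CC_i = 0`. The
#' network value is the unweighted mean over all n nodes.
#'
#' @param graph A `binary_graph` (or logical adjacency matrix).
#' @return List with `mean_cc`, per-node `cc`, and per-node triangle
#'   counts `t_i`.
#' @export
clustering_coefficient <- function(graph) {
  A <- as_adjacency(graph)
  An <- A * 1
  k <- rowSums(An)
  t_i <- diag(An %*% An %*% An) / 2
  cc <- ifelse(k < 2, 0, 2 * t_i / (k * (k - 1)))
  names(cc) <- rownames(A)
  list(mean_cc = mean(cc), cc = cc, t_i = t_i)
}

#' All-pairs shortest-path distances in hops
#'
#' Breadth-first search from every node; unreachable pairs are `Inf`.
#'
#' @param graph A `binary_graph` (or logical adjacency matrix).
#' @return Numeric n x n matrix of hop distances (0 on the diagonal).
#' @export
shortest_path_matrix <- function(graph) {
  A <- as_adjacency(graph)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  neighbors <- apply(A, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(neighbors[frontier]))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

#' Characteristic path length
#'
#' Mean shortest-path distance between node pairs:
#' `CPL = (1/n) sum_i sum_{j != i} d_ij / (n - 1)`. On disconnected graphs
#' the average is taken over reachable pairs only (per node, the mean over
#' its reachable partners); isolated nodes contribute 0 with a warning. An
#' edgeless graph has no defined CPL and returns `NA` with a warning.
#'
#' @param graph A `binary_graph` (or logical adjacency matrix).
#' @param distances Optional precomputed [shortest_path_matrix()].
#' @return CPL in hops, or `NA_real_` for an edgeless graph.
#' @export
characteristic_path_length <- function(graph, distances = NULL) {
  D <- if (is.null(distances)) shortest_path_matrix(graph) else distances
  n <- nrow(D)
  if (n < 2 || !any(is.finite(D) & D > 0)) {
    plv_warn("undefined_cpl", "graph has no edges; CPL undefined")
    return(NA_real_)
  }
  per_node <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else mean(d)  # isolated node contributes 0
  }, numeric(1))
  if (any(per_node == 0))
    plv_warn("isolated_nodes", "%d isolated node(s) contribute 0 to CPL",
             sum(per_node == 0))
  mean(per_node)
}

#' Node degrees
#'
#' @param graph A `binary_graph` (or logical adjacency matrix).
#' @return Named integer vector of degrees, in channel order.
#' @export
node_degrees <- function(graph) {
  A <- as_adjacency(graph)
  k <- as.integer(rowSums(A))
  names(k) <- rownames(A)
  k
}

#' All network metrics of one binary graph
#'
#' Convenience wrapper returning the quantities used downstream: mean
#' clustering coefficient, characteristic path length, per-node degrees,
#' triangle counts and the distance matrix.
#'
#' @param graph A `binary_graph`.
#' @return Object of class `network_metrics`.
#' @export
network_metrics <- function(graph) {
  cc <- clustering_coefficient(graph)
  D <- shortest_path_matrix(graph)
  cpl <- withCallingHandlers(
    characteristic_path_length(graph, D),
    plvnet_warning = function(w) invokeRestart("muffleWarning")
  )
  structure(list(mean_cc = cc$mean_cc, cc = cc$cc, t_i = cc$t_i,
                 cpl = cpl, degrees = node_degrees(graph),
                 d_ij = D, n_nodes = nrow(D), source = graph$source),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics: n = %d, mean CC = %.3f, CPL = %s>\n",
              x$n_nodes, x$mean_cc,
              if (is.na(x$cpl)) "NA" else sprintf("%.3f", x$cpl)))
  invisible(x)
}
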