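# Weighted graph metrics on fully weighted connectivity matrices: nodal
# and global efficiency via inverse shortest path lengths (edge length =
# 1/weight), and nodal/average weighted clustering coefficients.

#' Convert connectivity weights to edge lengths
#'
#' `length = 1 / weight` for positive weights; zero-weight pairs have no
#' direct edge (infinite direct length).
#'
#' @param cm A `"connectivity_matrix"`, or a plain symmetric weight matrix
#'   with entries in `[0, 1]`.
#' @return Numeric matrix of edge lengths (`Inf` off-diagonal where the
#'   weight is 0; diagonal 0).
#' @export
weights_to_lengths <- function(cm) {
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else cm
  if (min(w) < 0 || max(w) > 1)
    stop("weights must lie in [0, 1]", call. = FALSE)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

#' All-pairs weighted shortest path lengths
#'
#' Exact shortest paths (Dijkstra via igraph) on a symmetric non-negative
#' edge-length matrix; `Inf` marks disconnected pairs.
#'
#' @param lengths Symmetric edge-length matrix (`Inf` = absent edge,
#'   diagonal 0), e.g. from [weights_to_lengths()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_paths_matrix <- function(lengths) {
  if (any(lengths < 0, na.rm = TRUE))
    stop("edge lengths must be non-negative", call. = FALSE)
  n <- nrow(lengths)
  adj <- lengths
  adj[!is.finite(adj)] <- 0          # igraph: 0 = no edge here
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(lengths)
  d
}

#' Nodal efficiency
#'
#' `NE_i = 1/(N-1) * sum_{j != i} 1/d_ij`, with `1/Inf = 0` for
#' disconnected pairs: the average inverse shortest path length from node
#' i, a measure of its information-exchange efficiency.
#'
#' @param dm Distance matrix from [shortest_paths_matrix()].
#' @return Named numeric vector of per-node efficiencies in `[0, 1]` for
#'   weights in `[0, 1]`.
#' @export
nodal_efficiency <- function(dm) {
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  inv <- 1 / dm
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

#' Global efficiency
#'
#' Arithmetic mean of the nodal efficiencies: the network's integrated
#' information-transfer capacity.
#'
#' @param ne Numeric vector of nodal efficiencies.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(ne) mean(ne)

#' Weighted nodal clustering coefficient
#'
#' Quantifies how interconnected a node's neighbourhood is.  Two standard
#' weighted generalizations are offered:
#' \describe{
#'   \item{`"zhang"`}{Zhang-Horvath:
#'     `NCC_i = sum_{j != k} w_ij w_jk w_ki / ((sum_j w_ij)^2 - sum_j w_ij^2)`,
#'     bounded in `[0, 1]` for weights in `[0, 1]`.}
#'   \item{`"onnela"`}{Onnela: mean over neighbour pairs of the triangle's
#'     geometric-mean weight, `2/(k_i (k_i - 1)) * sum (w_ij w_jk w_ki)^(1/3)`
#'     over distinct neighbour pairs j < k of i (binary degree `k_i`).}
#' }
#' Nodes with fewer than two (positively weighted) neighbours get 0.
#'
#' @param cm A `"connectivity_matrix"` or plain symmetric weight matrix
#'   with entries in `[0, 1]`.
#' @param variant `"zhang"` (default) or `"onnela"`.
#' @return Named numeric vector of per-node clustering coefficients.
#' @export
nodal_clustering <- function(cm, variant = c("zhang", "onnela")) {
  variant <- match.arg(variant)
  w <- if (inherits(cm, "connectivity_matrix")) cm$weights else cm
  if (min(w) < 0 || max(w) > 1)
    stop("weights must lie in [0, 1]", call. = FALSE)
  diag(w) <- 0
  n <- nrow(w)
  if (variant == "zhang") {
    num <- diag(w %*% w %*% w)               # sum_{j,k} w_ij w_jk w_ki
    s1 <- rowSums(w)
    s2 <- rowSums(w^2)
    den <- s1^2 - s2
    ncc <- ifelse(den > 0, num / den, 0)
  } else {
    w3 <- w^(1 / 3)
    num <- diag(w3 %*% w3 %*% w3)
    k <- rowSums(w > 0)
    den <- k * (k - 1)
    ncc <- ifelse(den > 0, num / den, 0)
  }
  names(ncc) <- rownames(w)
  ncc
}

#' Average clustering coefficient
#'
#' Arithmetic mean of the nodal clustering coefficients.
#'
#' @param ncc Numeric vector of nodal clustering coefficients.
#' @return Scalar average clustering.
#' @export
average_clustering <- function(ncc) mean(ncc)

#' Aggregate a per-node metric by lobe
#'
#' Mean of the metric over each lobe's channels: frontal (FP1, FP2, F3,
#' F4), temporal (F7, T3, T5, F8, T4, T6), parietal (C3, C4, P3, P4),
#' occipital (O1, O2).
#'
#' @param values Named numeric vector over all 16 montage channels.
#' @param lobes Channel -> lobe map (default [montage_lobes()]).
#' @return Named numeric vector of lobe means (frontal, occipital,
#'   parietal, temporal order).
#' @export
lobe_aggregate <- function(values, lobes = montage_lobes()) {
  unknown <- setdiff(names(values), names(lobes))
  if (length(unknown) || is.null(names(values)))
    stop("unknown channel label(s): ",
         paste(unknown %||% "<unnamed>", collapse = ", "), call. = FALSE)
  miss <- setdiff(names(lobes), names(values))
  if (length(miss))
    stop("metric missing for channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lobe_names <- sort(unique(lobes))
  vapply(stats::setNames(nm = lobe_names), function(l)
    mean(values[names(lobes)[lobes == l]]), 0)
}

#' Full graph-metric summary of a connectivity matrix
#'
#' Computes nodal efficiency, global efficiency, nodal clustering, average
#' clustering and the four lobe aggregates of the nodal metrics.
#'
#' @param cm A `"connectivity_matrix"`.
#' @param clustering Clustering variant, see [nodal_clustering()].
#' @return A list of class `"graph_metrics"`: `GE`, `Cave`, `NE` (vector),
#'   `NCC` (vector), `lobe_NE`, `lobe_NCC`, `clustering_variant`.
#' @export
graph_metrics <- function(cm, clustering = c("zhang", "onnela")) {
  clustering <- match.arg(clustering)
  stopifnot(inherits(cm, "connectivity_matrix"))
  dm <- shortest_paths_matrix(weights_to_lengths(cm))
  ne <- nodal_efficiency(dm)
  ncc <- nodal_clustering(cm, clustering)
  full_montage <- setequal(cm$channel_labels, montage_channels())
  structure(list(GE = global_efficiency(ne), Cave = average_clustering(ncc),
                 NE = ne, NCC = ncc,
                 lobe_NE = if (full_montage) lobe_aggregate(ne),
                 lobe_NCC = if (full_montage) lobe_aggregate(ncc),
                 clustering_variant = clustering),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("<graph_metrics> GE = %.4f, Cave = %.4f (%s clustering)\n",
              x$GE, x$Cave, x$clustering_variant))
  invisible(x)
}
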