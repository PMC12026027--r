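as_adjacency <- function(net) {
  A <- if (inherits(net, "binary_network")) net$A else as.matrix(net)
  if (!isSymmetric(unname(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  A
}

#' Nodal graph metrics on a binary network
#'
#' Computes, per node, the five standard binary-graph properties used for
#' hemispheric comparison:
#' * degree `k_i` (row sum of the adjacency);
#' * clustering coefficient `C_i = 2 e_i / (k_i (k_i - 1))` (0 when
#'   `k_i < 2`), with `e_i` the number of edges among node i's neighbours;
#' * nodal path length `l_i`: mean shortest-path hop distance from i to the
#'   reachable nodes (NaN for isolated nodes);
#' * local efficiency: mean of `1 / d_jk` over ordered pairs of i's
#'   neighbours, distances taken in the subgraph induced by those
#'   neighbours (0 for degree < 2; unreachable pairs contribute 0);
#' * betweenness centrality: sum over unordered node pairs of the fraction
#'   of shortest paths passing through the node (endpoints excluded,
#'   unnormalized).
#'
#' Shortest paths are unweighted hop counts (breadth-first search via
#' igraph).
#'
#' @param net A [threshold_top_fraction()] result or symmetric 0/1 matrix.
#' @return `data.frame` with columns `node`, `degree`, `clustering`,
#'   `path_length`, `local_efficiency`, `betweenness`.
#' @export
node_metrics <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  k <- rowSums(A)
  clustering <- vapply(seq_len(n), function(i) {
    if (k[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    e_i <- sum(A[nb, nb]) / 2
    2 * e_i / (k[i] * (k[i] - 1))
  }, 0)
  path_length <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) NaN else mean(d)
  }, 0)
  local_eff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    Ds <- igraph::distances(sub)
    inv <- 1 / Ds[upper.tri(Ds)]
    inv[!is.finite(inv)] <- 0
    # ordered-pair mean = unordered-pair mean for a symmetric distance
    mean(inv)
  }, 0)
  betweenness <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  data.frame(node = if (!is.null(rownames(A))) rownames(A) else
               as.character(seq_len(n)),
             degree = as.numeric(k), clustering = clustering,
             path_length = path_length, local_efficiency = local_eff,
             betweenness = as.numeric(betweenness),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Characteristic path length over a node subset
#'
#' Mean shortest-path hop distance over ordered pairs of distinct nodes in
#' `nodes`, with distances measured on the full graph. Unreachable pairs
#' are excluded from the average; their count is returned as attribute
#' `n_excluded` (a finite alternative to infinite distances on sparse
#' proportionally-thresholded graphs). Set `mode = "harmonic"` to average
#' inverse distances instead (unreachable pairs contribute 0) and return
#' the reciprocal.
#'
#' @param net Binary network or adjacency matrix.
#' @param nodes Node names or indices (default: all).
#' @param mode `"exclude"` (default) or `"harmonic"`.
#' @return Scalar path length with attribute `n_excluded`.
#' @export
global_path_length <- function(net, nodes = NULL, mode = c("exclude", "harmonic")) {
  mode <- match.arg(mode)
  A <- as_adjacency(net)
  if (is.null(nodes)) nodes <- seq_len(nrow(A))
  if (is.character(nodes)) {
    nodes <- match(nodes, rownames(A))
    if (anyNA(nodes)) stop("unknown node names in subset")
  }
  if (length(nodes) < 2) stop("subset must contain at least 2 nodes")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)[nodes, nodes]
  d <- D[row(D) != col(D)]
  n_exc <- sum(!is.finite(d))
  L <- if (mode == "exclude") {
    fin <- d[is.finite(d)]
    if (!length(fin)) NaN else mean(fin)
  } else {
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    1 / mean(inv)
  }
  structure(L, n_excluded = n_exc)
}

#' Hemispheric summary of network properties
#'
#' Averages the five nodal metrics over the 15 key electrodes of each
#' hemisphere (means `KL, CL, LL, EL, BCL` on the left and `KR, CR, LR,
#' ER, BCR` on the right), computes the characteristic path length `L`
#' over the union of the 30 key electrodes, and the left-minus-right
#' differences `KD, CD, LD, ED, BCD`.
#'
#' @param metrics A [node_metrics()] table for the same network.
#' @param net The binary network (needed for `L`).
#' @param left,right Electrode sets of 15 names each (defaults:
#'   [hemisphere_electrodes()]).
#' @return Named numeric vector with elements `KL, CL, LL, EL, BCL, KR,
#'   CR, LR, ER, BCR, L, KD, CD, LD, ED, BCD`.
#' @export
hemisphere_summary <- function(metrics, net,
                               left = hemisphere_electrodes("left"),
                               right = hemisphere_electrodes("right")) {
  if (length(left) != 15 || length(right) != 15)
    stop("hemisphere electrode sets must contain exactly 15 electrodes")
  if (length(intersect(left, right)))
    stop("hemisphere sets must be disjoint")
  miss <- setdiff(c(left, right), metrics$node)
  if (length(miss)) stop("electrodes missing from metrics: ",
                         paste(miss, collapse = ", "))
  hemi_means <- function(set) {
    m <- metrics[match(set, metrics$node), ]
    pl <- m$path_length
    c(K = mean(m$degree), C = mean(m$clustering),
      L = mean(pl[is.finite(pl)]), E = mean(m$local_efficiency),
      BC = mean(m$betweenness))
  }
  l <- hemi_means(left)
  r <- hemi_means(right)
  L30 <- as.numeric(global_path_length(net, c(left, right)))
  out <- c(KL = l[["K"]], CL = l[["C"]], LL = l[["L"]], EL = l[["E"]],
           BCL = l[["BC"]],
           KR = r[["K"]], CR = r[["C"]], LR = r[["L"]], ER = r[["E"]],
           BCR = r[["BC"]],
           L = L30,
           KD = l[["K"]] - r[["K"]], CD = l[["C"]] - r[["C"]],
           LD = l[["L"]] - r[["L"]], ED = l[["E"]] - r[["E"]],
           BCD = l[["BC"]] - r[["BC"]])
  out
}
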