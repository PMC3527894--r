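# igraph views of a weighted_network.  Distance-mode edges carry their
# distance as the igraph weight; affinity-mode edges carry the affinity.
as_igraph <- function(net) {
  w <- net$weights
  present <- if (net$mode == "distance") is.finite(w) & w > 0 else w > 0
  present[lower.tri(present, diag = TRUE)] <- FALSE
  idx <- which(present, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(w), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$node_labels)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, as.vector(t(idx)))
    g <- igraph::set_edge_attr(g, "weight", value = w[idx])
  }
  g
}

#' Shortest-path statistics of a distance-weighted network
#'
#' All-pairs shortest paths under distance weights (Dijkstra). Averages are
#' taken over finite (within-component) pairs only; the `connected` flag
#' records whether any pair was unreachable. Global efficiency is the mean
#' of `1/d_ij` over ordered pairs with `1/Inf = 0`; the harmonic mean path
#' length is its reciprocal.
#'
#' @param net distance-mode `weighted_network`.
#' @return list with the `distances` matrix, per-node `eccentricity`, and a
#'   named `summary` vector (`avg_path_length`, `diameter`, `radius`,
#'   `harmonic_mean_path`, `global_efficiency`, `connected`).
#' @export
shortest_path_stats <- function(net) {
  check_mode(net, "distance")
  n <- length(net$node_labels)
  if (n == 0) stop("empty graph")
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  ecc <- vapply(seq_len(n), function(i) {
    vals <- d[i, -i][is.finite(d[i, -i])]
    if (length(vals) == 0) 0 else max(vals)
  }, numeric(1))
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  eff <- mean(ifelse(is.finite(off) & off > 0, 1 / off, 0))
  connected <- as.numeric(all(is.finite(off)) || n == 1)
  list(distances = d,
       eccentricity = stats::setNames(ecc, net$node_labels),
       summary = c(
         avg_path_length = if (length(finite)) mean(finite) else 0,
         diameter = if (n > 1) max(ecc) else 0,
         radius = if (n > 1) min(ecc) else 0,
         harmonic_mean_path = if (eff > 0) 1 / eff else 0,
         global_efficiency = eff,
         connected = connected))
}

#' Binary clustering coefficients
#'
#' Any positive-weight connection counts as an edge (weights set to unity);
#' the per-node coefficient is triangles over `choose(k, 2)`, defined as 0
#' for degree below 2. Works in either weight mode (presence is the same).
#'
#' @param net `weighted_network`.
#' @return named vector `clustering_mean`, `clustering_max`, `clustering_min`.
#' @export
clustering_coefficients <- function(net) {
  w <- net$weights
  a <- if (net$mode == "distance") is.finite(w) & w > 0 else w > 0
  a <- a * 1
  diag(a) <- 0
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  c(clustering_mean = mean(ci), clustering_max = max(ci),
    clustering_min = min(ci))
}

#' Weighted-degree features
#'
#' Per-node weighted degree `d_i = sum_j w_ij` on affinity weights, degree
#' summaries, and the entropy of the degree distribution
#' (`-sum p_i log p_i` with `p_i = d_i / sum d`, natural log; an all-zero
#' graph has entropy 0 with a warning).
#'
#' @param net affinity-mode `weighted_network`.
#' @return list with per-node `degrees` and a named `summary` vector
#'   (`degree_mean`, `degree_max`, `degree_min`, `degree_entropy`).
#' @export
degree_features <- function(net) {
  check_mode(net, "affinity")
  d <- rowSums(net$weights)
  s <- sum(d)
  if (s == 0) {
    warning("all-zero graph: degree entropy defined as 0")
    h <- 0
  } else {
    p <- d[d > 0] / s
    h <- -sum(p * log(p))
  }
  list(degrees = stats::setNames(d, net$node_labels),
       summary = c(degree_mean = mean(d), degree_max = max(d),
                   degree_min = min(d), degree_entropy = h))
}

#' Betweenness features and central point dominance
#'
#' Shortest-path betweenness on distance weights with fractional credit over
#' equal-length paths, normalised by `(n-1)(n-2)/2`. The per-node central
#' point dominance is `b'_max - b'_i` on the normalised values; the
#' graph-level value is their mean (Freeman's index). The betweenness
#' entropy treats the normalised values as a distribution (zero-sum gives 0).
#'
#' @param net distance-mode `weighted_network`.
#' @return list with per-node `betweenness` (normalised), per-node
#'   `dominance`, and a named `summary` vector (`betweenness_mean`,
#'   `betweenness_max`, `betweenness_min`, `betweenness_entropy`,
#'   `central_point_dominance`).
#' @export
betweenness_features <- function(net) {
  check_mode(net, "distance")
  n <- length(net$node_labels)
  g <- as_igraph(net)
  b <- igraph::betweenness(g, weights = igraph::E(g)$weight, directed = FALSE)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  bn <- as.numeric(b) / norm
  dom <- max(bn) - bn
  s <- sum(bn)
  h <- if (s > 0) { p <- bn[bn > 0] / s; -sum(p * log(p)) } else 0
  # Freeman's index sums the dominance over the n-1 non-maximal positions
  cpd <- if (n > 1) sum(dom) / (n - 1) else 0
  list(betweenness = stats::setNames(bn, net$node_labels),
       dominance = stats::setNames(dom, net$node_labels),
       summary = c(betweenness_mean = mean(bn), betweenness_max = max(bn),
                   betweenness_min = min(bn), betweenness_entropy = h,
                   central_point_dominance = cpd))
}

#' Degree assortativity over edges
#'
#' Pearson correlation of the weighted degrees of edge endpoints over all
#' present edges, each undirected edge counted in both orientations. When
#' the endpoint degrees have zero variance (e.g. a regular graph) the value
#' is undefined; 0 is returned with the `degenerate` flag set.
#'
#' @param net affinity-mode `weighted_network` with at least 2 edges.
#' @return named vector `assortativity`, `assortativity_degenerate`.
#' @export
assortativity_degree_weighted <- function(net) {
  check_mode(net, "affinity")
  w <- net$weights
  d <- rowSums(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("assortativity needs at least 2 edges")
  x <- c(d[idx[, 1]], d[idx[, 2]])
  y <- c(d[idx[, 2]], d[idx[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(assortativity = 0, assortativity_degenerate = 1))
  }
  c(assortativity = stats::cor(x, y), assortativity_degenerate = 0)
}
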