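#' Edge-weight (2-clique) features
#'
#' The upper triangle of the affinity matrix in row-major order, one feature
#' per node pair, named `edge_<label_i>__<label_j>` with `i < j` in the
#' canonical node order. A 116-node network yields 6,670 features.
#'
#' @param net affinity-mode `weighted_network`.
#' @return named numeric vector of length `n (n - 1) / 2`.
#' @export
edge_weight_features <- function(net) {
  check_mode(net, "affinity")
  n <- length(net$node_labels)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- net$weights[idx]
  names(vals) <- paste0("edge_", net$node_labels[idx[, 1]], "__",
                        net$node_labels[idx[, 2]])
  vals
}

#' Parse an edge-feature name back to its node pair
#'
#' @param name feature name produced by [edge_weight_features()].
#' @param node_labels the canonical node labels.
#' @return integer vector `c(i, j)` with `i < j`.
#' @export
parse_edge_feature <- function(name, node_labels) {
  body <- sub("^edge_", "", name)
  parts <- strsplit(body, "__", fixed = TRUE)[[1]]
  i <- match(parts[1], node_labels)
  j <- match(parts[2], node_labels)
  if (is.na(i) || is.na(j)) stop("edge feature name does not match node labels")
  c(i, j)
}

# run a feature block; on error return the documented degenerate defaults
# and set the block's failure flag
safe_block <- function(expr, defaults) {
  tryCatch(expr, error = function(e) defaults)
}

#' Full network-feature battery
#'
#' Runs every graph measure on one affinity network (the distance-mode view
#' is derived internally by reciprocal weights): shortest-path statistics,
#' clustering coefficients, degree and betweenness features, assortativity,
#' effective-resistance measures, spectral and isoperimetric separability,
#' minimum-cycle-basis summaries, the thresholded sparsity/fill-in grid, and
#' all pairwise edge weights. Per-node measures are emitted once per node
#' under node-labelled names; a failing block falls back to its documented
#' degenerate default and raises its `*_degenerate` flag feature.
#'
#' @param net affinity-mode `weighted_network`.
#' @return named numeric vector with a stable ordering and name set that
#'   depends only on the node labels.
#' @export
extract_all_features <- function(net) {
  check_mode(net, "affinity")
  labels <- net$node_labels
  dist_net <- to_distance_weights(net)

  paths <- shortest_path_stats(dist_net)
  clust <- clustering_coefficients(net)
  degs <- degree_features(net)
  btw <- betweenness_features(dist_net)
  asrt <- safe_block(assortativity_degree_weighted(net),
                     c(assortativity = 0, assortativity_degenerate = 1))
  res <- resistance_features(net)
  spec <- spectral_separability(net)
  iso <- isoperimetric_estimate(net)
  cyc <- min_cycle_basis_features(dist_net)
  spars <- sparsity_features(net)
  edges <- edge_weight_features(net)

  named_per_node <- function(prefix, v) {
    stats::setNames(as.numeric(v), paste0(prefix, "_", labels))
  }
  c(paths$summary,
    clust,
    degs$summary,
    btw$summary,
    asrt,
    res$summary["resistance_radius"], res$summary["resistance_diameter"],
    res$summary["kirchhoff_index"],
    spec,
    c(isoperimetric = iso$iso,
      isoperimetric_normalized = iso$iso_normalized),
    cyc,
    spars,
    named_per_node("degree", degs$degrees),
    named_per_node("betweenness", btw$betweenness),
    named_per_node("dominance", btw$dominance),
    named_per_node("path_eccentricity", paths$eccentricity),
    named_per_node("resistance_eccentricity", res$eccentricity),
    edges)
}
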