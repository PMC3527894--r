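# Minimum-weight cycle basis by Horton's candidate construction: one
# shortest-path tree per vertex, one candidate cycle per (vertex, edge)
# combination, greedy selection of GF(2)-independent cycles by ascending
# weight.  Distances provide the cycle weights.

#' Minimum cycle basis of a distance-weighted network
#'
#' @param net distance-mode `weighted_network`.
#' @return list with `cycles` (each a list of node indices in cycle order),
#'   `edge_counts`, `weights` (weighted lengths), and `dimension`
#'   (`|E| - |V| + components`).
#' @export
min_cycle_basis <- function(net) {
  check_mode(net, "distance")
  w <- net$weights
  n <- nrow(w)
  present <- is.finite(w) & w > 0
  present[lower.tri(present, diag = TRUE)] <- FALSE
  edges <- which(present, arr.ind = TRUE)
  m <- nrow(edges)
  n_comp <- length(unique(graph_components(is.finite(w) & w > 0)))
  dim_cycle <- m - n + n_comp
  if (dim_cycle <= 0) {
    return(list(cycles = list(), edge_counts = integer(0),
                weights = numeric(0), dimension = 0L))
  }
  edge_id <- matrix(0L, n, n)
  for (e in seq_len(m)) {
    edge_id[edges[e, 1], edges[e, 2]] <- e
    edge_id[edges[e, 2], edges[e, 1]] <- e
  }
  g <- as_igraph(net)
  # deterministic tie-breaking: perturb weights so every shortest path is
  # unique (Horton's candidate set then provably contains a minimum basis);
  # reported cycle weights use the true distances.
  ew <- igraph::E(g)$weight * (1 + 1e-12 * seq_len(m))

  path_weight <- function(nodes) {
    if (length(nodes) < 2) return(0)
    sum(w[cbind(nodes[-length(nodes)], nodes[-1])])
  }
  candidates <- list()
  for (v in seq_len(n)) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = v, to = igraph::V(g),
                             weights = ew, output = "vpath"))
    paths <- lapply(sp$vpath, as.integer)
    for (e in seq_len(m)) {
      x <- edges[e, 1]; y <- edges[e, 2]
      if (v == x || v == y) next
      px <- paths[[x]]; py <- paths[[y]]
      if (length(px) == 0 || length(py) == 0) next
      # Horton condition: the two tree paths share only the root v
      if (length(intersect(px[-1], py[-1])) > 0) next
      cyc_nodes <- c(px, rev(py)[-length(py)])
      if (length(cyc_nodes) < 3) next
      candidates[[length(candidates) + 1]] <- list(
        nodes = cyc_nodes,
        weight = path_weight(px) + path_weight(py) + w[x, y])
    }
  }
  if (length(candidates) == 0) {
    return(list(cycles = list(), edge_counts = integer(0),
                weights = numeric(0), dimension = as.integer(dim_cycle)))
  }
  # edge-incidence vectors over GF(2)
  to_edge_vec <- function(nodes) {
    vec <- rep(FALSE, m)
    k <- length(nodes)
    for (i in seq_len(k)) {
      a <- nodes[i]; b <- nodes[if (i == k) 1 else i + 1]
      id <- edge_id[a, b]
      if (id == 0) return(NULL)   # not a closed walk over present edges
      vec[id] <- xor(vec[id], TRUE)
    }
    vec
  }
  keys <- vapply(candidates, function(cc) {
    paste(sort(cc$nodes), collapse = "-")
  }, character(1))
  ord <- order(vapply(candidates, `[[`, 0, "weight"), keys)
  basis_vecs <- matrix(FALSE, 0, m)
  pivots <- integer(0)
  cycles <- list()
  for (ci in ord) {
    cand <- candidates[[ci]]
    vec <- to_edge_vec(cand$nodes)
    if (is.null(vec) || !any(vec)) next
    # reduce against selected cycles
    red <- vec
    for (bi in seq_along(pivots)) {
      if (red[pivots[bi]]) red <- xor(red, basis_vecs[bi, ])
    }
    if (!any(red)) next
    pivots <- c(pivots, which(red)[1])
    basis_vecs <- rbind(basis_vecs, red)
    cycles[[length(cycles) + 1]] <- cand
    if (length(cycles) == dim_cycle) break
  }
  list(cycles = lapply(cycles, `[[`, "nodes"),
       edge_counts = vapply(cycles, function(cc) length(cc$nodes), integer(1)),
       weights = vapply(cycles, `[[`, 0, "weight"),
       dimension = as.integer(dim_cycle))
}

#' Cycle-structure features
#'
#' Summaries of the minimum cycle basis under distance weights: the basis
#' dimension, the percentage of basis cycles that are not triangles (more
#' than 3 edges), the mean and maximum weighted length over those
#' non-triangle cycles (0 when there are none), and the total weighted
#' length of the whole basis.
#'
#' @param net distance-mode `weighted_network`.
#' @return named vector `cycle_dimension`, `cycle_pct_nontriangle`,
#'   `cycle_mean_nontriangle_len`, `cycle_max_nontriangle_len`,
#'   `cycle_total_len`.
#' @export
min_cycle_basis_features <- function(net) {
  basis <- min_cycle_basis(net)
  k <- length(basis$cycles)
  nontri <- basis$edge_counts > 3
  c(cycle_dimension = basis$dimension,
    cycle_pct_nontriangle = if (k > 0) 100 * mean(nontri) else 0,
    cycle_mean_nontriangle_len = if (any(nontri)) mean(basis$weights[nontri]) else 0,
    cycle_max_nontriangle_len = if (any(nontri)) max(basis$weights[nontri]) else 0,
    cycle_total_len = sum(basis$weights))
}
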