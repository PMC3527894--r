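# Symbolic elimination ("elimination game") on the network's sparsity
# pattern: eliminating a node pairwise-connects all its not-yet-eliminated
# neighbours.  The fill-in count equals the number of nonzeros created by a
# sparse Cholesky factorisation of the permuted Laplacian, by the classical
# elimination-game equivalence — working on the graph sidesteps the
# Laplacian's singularity.

elimination_orderings <- c("lexicographic", "amd", "cuthill_mckee",
                           "dulmage_mendelsohn")

ordering_permutation <- function(adj, method) {
  n <- nrow(adj)
  switch(method,
    lexicographic = seq_len(n),
    amd = {
      # greedy minimum degree on the evolving elimination graph, ties by index
      a <- adj
      alive <- rep(TRUE, n)
      perm <- integer(n)
      for (k in seq_len(n)) {
        deg <- rowSums(a[, alive, drop = FALSE])
        deg[!alive] <- Inf
        v <- which.min(deg)
        perm[k] <- v
        nb <- which(a[v, ] & alive)
        nb <- setdiff(nb, v)
        if (length(nb) > 1) a[nb, nb] <- TRUE
        diag(a) <- FALSE
        a[v, ] <- FALSE
        a[, v] <- FALSE
        alive[v] <- FALSE
      }
      perm
    },
    cuthill_mckee = {
      # reverse Cuthill-McKee: BFS from a minimum-degree start, neighbours
      # visited in ascending degree (ties by index), order reversed
      deg <- rowSums(adj)
      visited <- rep(FALSE, n)
      ordering <- integer(0)
      while (length(ordering) < n) {
        remaining <- which(!visited)
        start <- remaining[order(deg[remaining], remaining)][1]
        queue <- start
        visited[start] <- TRUE
        while (length(queue) > 0) {
          v <- queue[1]
          queue <- queue[-1]
          ordering <- c(ordering, v)
          nb <- which(adj[v, ] & !visited)
          nb <- nb[order(deg[nb], nb)]
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
      rev(ordering)
    },
    dulmage_mendelsohn = {
      # on a symmetric pattern with a structurally full diagonal the
      # bipartite decomposition's row permutation groups rows by the
      # diagonal blocks, i.e. by connected component of the pattern
      comp <- graph_components(adj | diag(TRUE, n))
      order(comp, seq_len(n))
    },
    stop(sprintf("unknown ordering method '%s'", method))
  )
}

#' Symbolic elimination fill-in under a node ordering
#'
#' Computes a node ordering by the requested strategy, then plays the
#' elimination game on the graph structure and counts the new edges
#' (fill-in) the ordering creates.
#'
#' @param net `weighted_network` (either mode; only edge presence matters).
#' @param ordering_method one of `"lexicographic"`, `"amd"` (greedy minimum
#'   degree), `"cuthill_mckee"` (reverse variant, minimum-degree start),
#'   `"dulmage_mendelsohn"` (component-block row permutation of the
#'   Laplacian pattern).
#' @return list with `permutation`, `ordering_method`, `fill_in`.
#' @export
elimination_fill_in <- function(net, ordering_method = "lexicographic") {
  stopifnot(inherits(net, "weighted_network"))
  if (!ordering_method %in% elimination_orderings) {
    stop(sprintf("unknown ordering method '%s'", ordering_method))
  }
  w <- net$weights
  adj <- if (net$mode == "distance") is.finite(w) & w > 0 else w > 0
  diag(adj) <- FALSE
  perm <- ordering_permutation(adj, ordering_method)
  fill <- symbolic_fill_count(adj, perm)
  list(permutation = perm, ordering_method = ordering_method,
       fill_in = fill)
}

symbolic_fill_count <- function(adj, perm) {
  n <- nrow(adj)
  a <- adj
  alive <- rep(TRUE, n)
  fill <- 0L
  for (v in perm) {
    nb <- which(a[v, ] & alive)
    nb <- setdiff(nb, v)
    if (length(nb) > 1) {
      block <- a[nb, nb, drop = FALSE]
      new_edges <- (sum(!block) - length(nb)) / 2
      fill <- fill + as.integer(new_edges)
      a[nb, nb] <- TRUE
      diag(a) <- FALSE
    }
    alive[v] <- FALSE
  }
  fill
}

#' Thresholded sparsity and fill-in feature grid
#'
#' For each affinity threshold `t` in `{0, 0.1, 0.3, 0.5, 0.7, 0.9}` the
#' network keeps edges with `w > t` and reports the surviving edge count
#' (the Laplacian's off-diagonal sparsity) plus the fill-in of all four
#' elimination orderings: 5 values per threshold, 30 features.
#'
#' @param net affinity-mode `weighted_network`.
#' @param thresholds affinity levels to threshold at.
#' @return named vector of length `5 * length(thresholds)`.
#' @export
sparsity_features <- function(net, thresholds = c(0, 0.1, 0.3, 0.5, 0.7, 0.9)) {
  check_mode(net, "affinity")
  out <- numeric(0)
  for (t in thresholds) {
    w <- net$weights
    w[w <= t] <- 0
    sub <- weighted_network(w, net$node_labels, mode = "affinity",
                            estimator = net$estimator)
    vals <- c(sum(w[upper.tri(w)] > 0),
              vapply(elimination_orderings, function(m) {
                elimination_fill_in(sub, m)$fill_in
              }, numeric(1)))
    names(vals) <- paste0(c("edges", paste0("fillin_", elimination_orderings)),
                          "_t", t)
    out <- c(out, vals)
  }
  out
}
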