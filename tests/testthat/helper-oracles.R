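# Independent brute-force implementations used as oracles for the graph
# measures.  All operate on a plain symmetric affinity matrix `w` (zero
# diagonal) and deliberately share no code with the package internals.

random_affinity <- function(n, p_edge = 0.6, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w[i, j] <- w[j, i] <- stats::runif(1, 0.1, 1)
      }
    }
  }
  w
}

is_connected_bf <- function(w) {
  n <- nrow(w)
  seen <- c(1)
  repeat {
    nb <- unique(unlist(lapply(seen, function(v) which(w[v, ] > 0))))
    grown <- union(seen, nb)
    if (length(grown) == length(seen)) break
    seen <- grown
  }
  length(seen) == n
}

# Floyd-Warshall on distance weights 1/w
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# fractional-credit betweenness by enumerating every simple path and
# keeping the shortest ones per pair
betweenness_bf <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  paths_between <- function(i, j) {
    found <- list()
    rec <- function(path, len) {
      v <- path[length(path)]
      if (v == j) {
        found[[length(found) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (u in which(is.finite(d[v, ]))) {
        if (u %in% path) next
        rec(c(path, u), len + d[v, u])
      }
    }
    rec(i, 0)
    found
  }
  b <- rep(0, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      all_p <- paths_between(i, j)
      if (length(all_p) == 0) next
      lens <- vapply(all_p, `[[`, 0, "len")
      short <- all_p[abs(lens - min(lens)) < 1e-12]
      for (p in short) {
        inner <- setdiff(p$path, c(i, j))
        b[inner] <- b[inner] + 1 / length(short)
      }
    }
  }
  b
}

resistance_bf <- function(w) {
  l <- diag(rowSums(w)) - w
  lp <- MASS::ginv(l)
  n <- nrow(w)
  outer(diag(lp), diag(lp), `+`) - 2 * lp
}

# exhaustive isoperimetric numbers over every nonempty subset
isoperimetric_bf <- function(w) {
  n <- nrow(w)
  d <- rowSums(w)
  vol_total <- sum(d)
  best_iso <- Inf
  best_nrm <- Inf
  for (mask in 1:(2^n - 2)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    cut_val <- sum(w[s, setdiff(seq_len(n), s), drop = FALSE])
    if (length(s) <= n / 2) {
      best_iso <- min(best_iso, cut_val / length(s))
    }
    vol_s <- sum(d[s])
    if (vol_s > 0 && vol_s <= vol_total / 2) {
      best_nrm <- min(best_nrm, cut_val / vol_s)
    }
  }
  c(iso = best_iso, nrm = best_nrm)
}

# every simple cycle (as an edge-index set) by rooted DFS, deduplicated
all_cycles_bf <- function(w) {
  n <- nrow(w)
  present <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(present)
  eid <- matrix(0L, n, n)
  for (e in seq_len(m)) {
    eid[present[e, 1], present[e, 2]] <- e
    eid[present[e, 2], present[e, 1]] <- e
  }
  cycles <- list()
  seen <- character(0)
  rec <- function(path) {
    v <- path[length(path)]
    for (u in which(w[v, ] > 0)) {
      if (u == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        edge_set <- sort(vapply(seq_along(path), function(i) {
          eid[path[i], path[if (i == length(path)) 1 else i + 1]]
        }, integer(1)))
        key <- paste(edge_set, collapse = ",")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1]] <<- edge_set
        }
      } else if (!u %in% path && u > path[1]) {
        rec(c(path, u))
      }
    }
  }
  for (v in seq_len(n)) rec(v)
  list(cycles = cycles, edges = present)
}

# minimum cycle basis total weight: greedy over ALL simple cycles
min_cycle_basis_bf <- function(w) {
  enum <- all_cycles_bf(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  m <- nrow(enum$edges)
  if (length(enum$cycles) == 0) {
    return(list(total = 0, dims = 0, lengths = numeric(0)))
  }
  weights <- vapply(enum$cycles, function(es) {
    sum(d[enum$edges[es, , drop = FALSE]])
  }, 0)
  ord <- order(weights)
  basis <- matrix(FALSE, 0, m)
  pivots <- integer(0)
  lens <- numeric(0)
  for (ci in ord) {
    vec <- rep(FALSE, m)
    vec[enum$cycles[[ci]]] <- TRUE
    red <- vec
    for (bi in seq_along(pivots)) {
      if (red[pivots[bi]]) red <- xor(red, basis[bi, ])
    }
    if (!any(red)) next
    pivots <- c(pivots, which(red)[1])
    basis <- rbind(basis, red)
    lens <- c(lens, weights[ci])
  }
  list(total = sum(lens), dims = length(lens), lengths = sort(lens))
}

# set-based symbolic elimination, independent of the package routine
fillin_bf <- function(w, perm) {
  n <- nrow(w)
  nbrs <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  eliminated <- logical(n)
  fill <- 0
  for (v in perm) {
    nb <- setdiff(nbrs[[v]], which(eliminated))
    if (length(nb) > 1) {
      for (a_i in seq_len(length(nb) - 1)) {
        for (b_i in (a_i + 1):length(nb)) {
          a <- nb[a_i]; b <- nb[b_i]
          if (!b %in% nbrs[[a]]) {
            fill <- fill + 1
            nbrs[[a]] <- c(nbrs[[a]], b)
            nbrs[[b]] <- c(nbrs[[b]], a)
          }
        }
      }
    }
    eliminated[v] <- TRUE
  }
  fill
}

# build a weighted_network directly from an affinity matrix
aff_net <- function(w, labels = NULL) {
  weighted_network(w, labels, mode = "affinity")
}
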