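#' Laplacian matrices of an affinity network
#'
#' Builds the weighted-degree matrix `D`, the unnormalised Laplacian
#' `L = D - W`, and the symmetric similarity transform of the random-walk
#' Laplacian, `D^{-1/2} L D^{-1/2}` (same spectrum as `D^{-1} L`). Isolated
#' nodes contribute zero rows to the normalised form.
#'
#' @param net affinity-mode `weighted_network`.
#' @return list with `W`, `degrees`, `L`, `Lnorm`.
#' @export
graph_matrices <- function(net) {
  check_mode(net, "affinity")
  w <- net$weights
  d <- rowSums(w)
  l <- diag(d) - w
  dn <- ifelse(d > 0, 1 / sqrt(d), 0)
  lnorm <- diag(dn) %*% l %*% diag(dn)
  lnorm <- (lnorm + t(lnorm)) / 2
  dimnames(l) <- dimnames(lnorm) <- dimnames(w)
  list(W = w, degrees = stats::setNames(d, net$node_labels), L = l, Lnorm = lnorm)
}

#' Spectral separability features
#'
#' Second- and third-smallest eigenvalues of the unnormalised and the
#' normalised Laplacian, sorted ascending with the structural zero first.
#' The second-smallest value (algebraic connectivity, the Fiedler value)
#' is 0 exactly when the graph is disconnected.
#'
#' @param mats output of [graph_matrices()], or an affinity network.
#' @return named vector `fiedler_L`, `third_eig_L`, `fiedler_Lnorm`,
#'   `third_eig_Lnorm`.
#' @export
spectral_separability <- function(mats) {
  if (inherits(mats, "weighted_network")) mats <- graph_matrices(mats)
  ev_l <- sort(eigen(mats$L, symmetric = TRUE, only.values = TRUE)$values)
  ev_n <- sort(eigen(mats$Lnorm, symmetric = TRUE, only.values = TRUE)$values)
  clip0 <- function(v) pmax(v, 0)   # symmetric PSD matrices; clip fp noise
  ev_l <- clip0(ev_l); ev_n <- clip0(ev_n)
  n <- length(ev_l)
  c(fiedler_L = if (n >= 2) ev_l[2] else 0,
    third_eig_L = if (n >= 3) ev_l[3] else 0,
    fiedler_Lnorm = if (n >= 2) ev_n[2] else 0,
    third_eig_Lnorm = if (n >= 3) ev_n[3] else 0)
}

#' Effective-resistance features
#'
#' Treats affinity weights as conductances; pairwise effective resistance is
#' `R_ij = L+_ii + L+_jj - 2 L+_ij` from the Moore-Penrose pseudoinverse of
#' the Laplacian. On disconnected networks the resistances are computed per
#' component (infinite cross-component resistances are excluded from the
#' summaries) and the `connected` flag is 0.
#'
#' @param net affinity-mode `weighted_network`.
#' @return list with the `resistance` matrix (Inf across components),
#'   per-node `eccentricity`, and a named vector `summary` containing
#'   `resistance_radius`, `resistance_diameter`, `kirchhoff_index`,
#'   `connected`.
#' @export
resistance_features <- function(net) {
  check_mode(net, "affinity")
  w <- net$weights
  n <- nrow(w)
  comp <- graph_components(w > 0)
  r <- matrix(Inf, n, n)
  diag(r) <- 0
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) next
    l <- diag(rowSums(w[idx, idx, drop = FALSE])) - w[idx, idx]
    lp <- pseudoinverse_sym(l)
    dg <- diag(lp)
    r[idx, idx] <- outer(dg, dg, `+`) - 2 * lp
  }
  r[r < 0] <- 0   # fp noise
  finite_off <- function(v) v[is.finite(v)]
  ecc <- vapply(seq_len(n), function(i) {
    vals <- finite_off(r[i, -i])
    if (length(vals) == 0) 0 else max(vals)
  }, numeric(1))
  ut <- r[upper.tri(r)]
  kirchhoff <- sum(finite_off(ut))
  connected <- as.numeric(length(unique(comp)) == 1 && n >= 1)
  list(resistance = r,
       eccentricity = stats::setNames(ecc, net$node_labels),
       summary = c(resistance_radius = if (n > 1) min(ecc) else 0,
                   resistance_diameter = if (n > 1) max(ecc) else 0,
                   kirchhoff_index = kirchhoff,
                   connected = connected))
}

# Moore-Penrose pseudoinverse of a symmetric matrix via eigendecomposition.
pseudoinverse_sym <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  pos <- abs(e$values) > tol * max(abs(e$values), 1)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# Connected-component labels of a logical adjacency matrix (BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Isoperimetric-number estimate by sweep cuts
#'
#' Estimates the (NP-hard) isoperimetric number `min cut(S, ~S) / |S|` over
#' subsets with `|S| <= n/2`, and its volume-normalised analogue
#' `min cut(S, ~S) / Vol(S)` over subsets with `Vol(S) <= Vol(V)/2`.
#' Candidate subsets are the prefixes of node orderings from (a) the Fiedler
#' vectors of the unnormalised and normalised Laplacians (spectral sweep)
#' and (b) the isoperimetric-clustering potential solving the grounded
#' system `L0 x = d` with the maximum-degree node grounded. Disconnected
#' networks return 0 for both values, by definition.
#'
#' @param net affinity-mode `weighted_network`.
#' @return list with `iso`, `iso_normalized`, and the minimising subsets
#'   (`subset_iso`, `subset_iso_normalized`, as node indices).
#' @export
isoperimetric_estimate <- function(net) {
  check_mode(net, "affinity")
  w <- net$weights
  n <- nrow(w)
  comp <- graph_components(w > 0)
  if (length(unique(comp)) > 1 || n < 2) {
    return(list(iso = 0, iso_normalized = 0,
                subset_iso = integer(0), subset_iso_normalized = integer(0),
                connected = FALSE))
  }
  mats <- graph_matrices(net)
  d <- mats$degrees
  orders <- list()
  ev <- eigen(mats$L, symmetric = TRUE)
  orders$fiedler <- order(ev$vectors[, n - 1], seq_len(n))
  evn <- eigen(mats$Lnorm, symmetric = TRUE)
  # map the symmetric-form eigenvector back to the random-walk eigenvector
  vn <- evn$vectors[, n - 1]
  dn <- ifelse(d > 0, 1 / sqrt(d), 0)
  orders$fiedler_norm <- order(vn * dn, seq_len(n))
  ground <- which.max(d)
  keep <- setdiff(seq_len(n), ground)
  l0 <- mats$L[keep, keep, drop = FALSE]
  x <- rep(0, n)
  pot <- try(solve(l0, d[keep]), silent = TRUE)
  if (!inherits(pot, "try-error")) {
    x[keep] <- pot
    orders$isoperimetric <- order(x, seq_len(n))
  }

  best <- list(iso = Inf, iso_set = integer(0),
               nrm = Inf, nrm_set = integer(0))
  vol_total <- sum(d)
  for (ord in orders) {
    cut_val <- 0
    in_s <- rep(FALSE, n)
    vol_s <- 0
    for (k in seq_len(n - 1)) {
      v <- ord[k]
      # moving v into S flips its edges: to outside +, to inside -
      cut_val <- cut_val + sum(w[v, !in_s]) - sum(w[v, in_s])
      in_s[v] <- TRUE
      vol_s <- vol_s + d[v]
      s_small <- if (k <= n - k) which(in_s) else which(!in_s)
      size_small <- min(k, n - k)
      iso_k <- cut_val / size_small
      if (iso_k < best$iso) {
        best$iso <- iso_k
        best$iso_set <- s_small
      }
      vol_small <- min(vol_s, vol_total - vol_s)
      if (vol_small > 0) {
        nrm_k <- cut_val / vol_small
        if (nrm_k < best$nrm) {
          best$nrm <- nrm_k
          best$nrm_set <- if (vol_s <= vol_total - vol_s) which(in_s) else which(!in_s)
        }
      }
    }
  }
  list(iso = best$iso, iso_normalized = best$nrm,
       subset_iso = best$iso_set, subset_iso_normalized = best$nrm_set,
       connected = TRUE)
}
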