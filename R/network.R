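#' Weighted undirected connectivity network
#'
#' Symmetric nonnegative weight matrix over labelled nodes, with a mode flag
#' distinguishing affinity weights (connection strength, conductance) from
#' distance weights (their reciprocals, resistance). In distance mode an
#' absent edge is `Inf`, never 0.
#'
#' @param weights n x n symmetric numeric matrix with zero diagonal.
#' @param node_labels character vector of n unique node names.
#' @param mode `"affinity"` or `"distance"`.
#' @param estimator which construction produced the weights
#'   (`"corr"`, `"sic"`, `"kappa"`, or `"manual"`).
#' @param signed optional matrix of the signed estimates retained as
#'   metadata (the affinity weights themselves are magnitudes).
#' @return object of class `weighted_network`.
#' @export
weighted_network <- function(weights, node_labels = NULL,
                             mode = c("affinity", "distance"),
                             estimator = "manual", signed = NULL) {
  mode <- match.arg(mode)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weight matrix must be square")
  if (is.null(node_labels)) {
    node_labels <- rownames(weights)
    if (is.null(node_labels)) node_labels <- roi_labels(n)
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != n || anyDuplicated(node_labels)) {
    stop("need one unique label per node")
  }
  if (max(abs(weights - t(weights)), na.rm = TRUE) > 1e-9) {
    stop("weight matrix must be symmetric")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- if (mode == "affinity") 0 else 0
  finite <- weights[is.finite(weights)]
  if (any(finite < 0)) stop("weights must be nonnegative magnitudes")
  if (mode == "distance" && any(weights[upper.tri(weights)] == 0)) {
    stop("a distance-mode network encodes absent edges as Inf, not 0")
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(weights = weights, node_labels = node_labels, mode = mode,
         estimator = estimator, signed = signed),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  n_edges <- if (x$mode == "affinity") sum(ut > 0) else sum(is.finite(ut))
  cat(sprintf("<weighted_network> %d nodes, %d edges, %s weights (%s estimator)\n",
              length(x$node_labels), n_edges, x$mode, x$estimator))
  invisible(x)
}

check_mode <- function(net, mode) {
  stopifnot(inherits(net, "weighted_network"))
  if (net$mode != mode) {
    stop(sprintf("this operation consumes %s weights but the network is in %s mode",
                 mode, net$mode))
  }
  invisible(net)
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate (default 0.01).
#' @return logical vector marking rejected hypotheses.
#' @export
bh_fdr <- function(pvalues, q = 0.01) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Correlation network with autocorrelation-aware FDR thresholding
#'
#' Pairwise Pearson correlations are Fisher-transformed to two-sided
#' p-values using the pair's effective sample size (see [effective_df()]),
#' corrected by Benjamini-Hochberg at rate `q`. Surviving edges receive
#' affinity weight `|r|`; all others are 0. Constant regions are isolated
#' with a warning.
#'
#' @param ts `roi_timeseries` with at least 8 timepoints.
#' @param q false-discovery rate (default 0.01).
#' @return affinity-mode `weighted_network` with the signed correlations in
#'   `$signed`.
#' @export
build_corr_network <- function(ts, q = 0.01) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  n_t <- nrow(x)
  if (n_t < 8) stop("need at least 8 timepoints")
  n <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sprintf("constant region series isolated: %s",
                    paste(ts$region_labels[constant], collapse = ", ")))
  }
  r <- matrix(0, n, n)
  ok <- which(!constant)
  if (length(ok) >= 2) r[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
  diag(r) <- 0

  ut <- which(upper.tri(r), arr.ind = TRUE)
  pvals <- rep(1, nrow(ut))
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    if (constant[i] || constant[j]) next
    t_eff <- effective_df(x[, i], x[, j])
    z <- atanh(min(max(r[i, j], -1 + 1e-12), 1 - 1e-12)) * sqrt(t_eff - 3)
    pvals[k] <- 2 * stats::pnorm(-abs(z))
  }
  keep <- bh_fdr(pvals, q)
  w <- matrix(0, n, n)
  w[ut[keep, , drop = FALSE]] <- abs(r[ut[keep, , drop = FALSE]])
  w <- w + t(w)
  weighted_network(w, ts$region_labels, mode = "affinity",
                   estimator = "corr", signed = r)
}

#' Sparse inverse-covariance (graphical-lasso) network
#'
#' Estimates a sparse precision matrix by maximising
#' `log det(Theta) - tr(S Theta) - lambda * ||Theta||_1(off-diagonal)` via
#' block coordinate descent, on internally standardised series (so S is the
#' correlation matrix). The affinity weight of an edge is the partial
#' correlation magnitude `|-Theta_ij / sqrt(Theta_ii Theta_jj)|`, which lies
#' in `[0, 1]`. Entries below `1e-8` are snapped to zero to make the sparsity
#' pattern unambiguous.
#'
#' @param ts `roi_timeseries` with more timepoints than 2.
#' @param lam L1 penalty (default 0.1).
#' @param tol convergence tolerance on the working covariance (default 1e-4).
#' @param max_iter maximum outer sweeps (default 500).
#' @return affinity-mode `weighted_network`; signed partial correlations in
#'   `$signed`, the precision estimate in `$precision`.
#' @export
build_sic_network <- function(ts, lam = 0.1, tol = 1e-4, max_iter = 500) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  if (nrow(x) <= 2) stop("need more than 2 timepoints")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stop("constant region series cannot be standardised")
  s <- stats::cor(x)
  fit <- .glasso_cpp(s, lambda = lam, tol = tol, max_iter = max_iter)
  if (!fit$converged) {
    stop(sprintf("graphical lasso did not converge in %d iterations (lambda = %g)",
                 fit$iterations, lam))
  }
  theta <- fit$Theta
  d <- sqrt(diag(theta))
  pcor <- -theta / outer(d, d)
  diag(pcor) <- 0
  pcor[abs(pcor) < 1e-8] <- 0
  net <- weighted_network(abs(pcor), ts$region_labels, mode = "affinity",
                          estimator = "sic", signed = pcor)
  net$precision <- theta
  net
}

#' Patel's kappa for a pair of unit-interval series
#'
#' Both series are expected already rescaled to `[0, 1]`. With
#' `theta1 = mean(a*b)`, `p1 = mean(a)`, `p2 = mean(b)`, `E = p1*p2`, the
#' normaliser is `D = min(p1, p2) - E` when `theta1 >= E` and
#' `E - max(0, p1 + p2 - 1)` otherwise; `kappa = (theta1 - E) / D`.
#' Pairs with `D = 0` get kappa 0.
#'
#' @param a,b numeric vectors in `[0, 1]` of equal length.
#' @return scalar kappa in `[-1, 1]`.
#' @export
patel_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  theta1 <- mean(a * b)
  p1 <- mean(a)
  p2 <- mean(b)
  e <- p1 * p2
  d <- if (theta1 >= e) min(p1, p2) - e else e - max(0, p1 + p2 - 1)
  if (d <= 0) return(0)
  (theta1 - e) / d
}

#' Kappa connectivity network
#'
#' Each region's series is min-max rescaled to `[0, 1]`; edge affinities are
#' `|kappa|` for every pair ([patel_kappa()]). No edge threshold is applied:
#' kappa networks keep continuous-valued weights on all pairs. Constant
#' (zero-range) regions are isolated with a warning.
#'
#' @param ts `roi_timeseries`.
#' @return affinity-mode `weighted_network` with signed kappas in `$signed`.
#' @export
build_kappa_network <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  n <- ncol(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  constant <- rng == 0
  if (any(constant)) {
    warning(sprintf("constant region series isolated: %s",
                    paste(ts$region_labels[constant], collapse = ", ")))
  }
  u <- x
  for (j in which(!constant)) {
    u[, j] <- (x[, j] - min(x[, j])) / rng[j]
  }
  k <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    if (constant[i]) next
    for (j in (i + 1):n) {
      if (constant[j]) next
      k[i, j] <- patel_kappa(u[, i], u[, j])
      k[j, i] <- k[i, j]
    }
  }
  weighted_network(abs(k), ts$region_labels, mode = "affinity",
                   estimator = "kappa", signed = k)
}

#' Convert between affinity and distance weight modes
#'
#' Distance (resistance) is the reciprocal of affinity (conductance):
#' `w_distance = 1 / w_affinity`. Zero-affinity pairs become non-edges
#' (infinite distance). `to_affinity_weights` is the inverse map.
#'
#' @param net `weighted_network` in affinity mode.
#' @return the same network in distance mode.
#' @export
to_distance_weights <- function(net) {
  check_mode(net, "affinity")
  w <- net$weights
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  out <- net
  out$weights <- d
  out$mode <- "distance"
  out
}

#' @rdname to_distance_weights
#' @export
to_affinity_weights <- function(net) {
  check_mode(net, "distance")
  d <- net$weights
  w <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(w) <- 0
  out <- net
  out$weights <- w
  out$mode <- "affinity"
  out
}
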