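test_that("Benjamini-Hochberg step-up rejects exactly the right hypotheses", {
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))
  # hand-applied step-up: sorted p (0.001, 0.008, 0.04, 0.6) against
  # 0.05 * k/4 = (0.0125, 0.025, 0.0375, 0.05): largest passing k is 2
  mask <- bh_fdr(c(0.001, 0.008, 0.04, 0.6), 0.05)
  expect_identical(mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(bh_fdr(0.005, 0.01))
  expect_false(bh_fdr(0.02, 0.01))
})

test_that("correlation network keeps a perfectly correlated pair with weight ~1", {
  set.seed(7)
  base <- rnorm(200)
  ts <- roi_timeseries(cbind(a = base, b = base + rnorm(200, sd = 1e-6),
                             c = rnorm(200)), tr = 2)
  net <- build_corr_network(ts, q = 0.01)
  expect_equal(net$weights["a", "b"], 1, tolerance = 1e-3)
  expect_identical(net$mode, "affinity")
  expect_true(all(diag(net$weights) == 0))
})

test_that("corr edge selection matches hand-computed Fisher p-values + BH", {
  set.seed(123)
  n_t <- 120
  shared <- rnorm(n_t)
  x <- cbind(a = shared + rnorm(n_t, sd = 0.8),
             b = shared + rnorm(n_t, sd = 0.8),
             c = rnorm(n_t), d = rnorm(n_t))
  ts <- roi_timeseries(x, tr = 2)
  q <- 0.01
  # oracle: recompute every pair's p by the closed form and apply the
  # step-up rule by hand
  pairs <- combn(4, 2)
  p <- apply(pairs, 2, function(ij) {
    r <- cor(x[, ij[1]], x[, ij[2]])
    t_eff <- effective_df(x[, ij[1]], x[, ij[2]])
    2 * pnorm(-abs(atanh(r) * sqrt(t_eff - 3)))
  })
  ord <- order(p)
  passed <- which(p[ord] <= q * seq_along(p) / length(p))
  keep <- logical(length(p))
  if (length(passed) > 0) keep[ord[seq_len(max(passed))]] <- TRUE
  net <- build_corr_network(ts, q = q)
  got <- apply(pairs, 2, function(ij) net$weights[ij[1], ij[2]] > 0)
  expect_identical(got, keep)
  expect_true(net$weights["a", "b"] > 0)   # the planted correlation survives
})

test_that("constant regions are isolated with a warning", {
  ts <- roi_timeseries(cbind(a = rnorm(100), b = rep(2, 100), c = rnorm(100)),
                       tr = 2)
  expect_warning(net <- build_corr_network(ts), "constant")
  expect_true(all(net$weights["b", ] == 0))
  expect_warning(netk <- build_kappa_network(ts), "constant")
  expect_true(all(netk$weights["b", ] == 0))
})

test_that("graphical lasso reproduces an independent reference solution", {
  # reference precision computed with an independent graphical-lasso
  # implementation (scikit-learn, alpha = 0.1, off-diagonal penalty)
  s <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.3,
                0.2, 0.3, 1), 3, 3)
  ref <- matrix(c(1.1910429094, -0.4714335102, -0.0248038938,
                  -0.4714335102, 1.2282333275, -0.1984267954,
                  -0.0248038938, -0.1984267954, 1.0421490818), 3, 3)
  fit <- fcdiag:::.glasso_cpp(s, 0.1, tol = 1e-7, max_iter = 1000)
  expect_true(fit$converged)
  expect_equal(fit$Theta, ref, tolerance = 5e-4)
})

test_that("graphical-lasso KKT optimality holds at the solution", {
  set.seed(11)
  x <- matrix(rnorm(200 * 6), 200, 6)
  s <- cor(x)
  lam <- 0.15
  fit <- fcdiag:::.glasso_cpp(s, lam, tol = 1e-6, max_iter = 1000)
  theta <- fit$Theta
  w <- solve(theta)
  # stationarity: W - S = lam * sign(Theta) on active off-diagonals,
  # |W - S| <= lam where Theta is 0; diagonal unpenalised (W_ii = S_ii)
  resid <- w - s
  off <- upper.tri(s)
  active <- off & abs(theta) > 1e-7
  expect_lt(max(abs(resid[off & !active])), lam + 1e-4)
  if (any(active)) {
    expect_equal(resid[active], lam * sign(theta[active]), tolerance = 1e-3)
  }
  expect_equal(diag(w), diag(s), tolerance = 1e-6)
})

test_that("SIC network shrinks fully at large lambda and recovers planted support", {
  set.seed(3)
  # full shrinkage
  ts <- roi_timeseries(matrix(rnorm(500 * 5), 500, 5), tr = 2)
  net <- build_sic_network(ts, lam = 5)
  expect_true(all(net$weights == 0))

  # 3 regions, one conditional dependency with partial correlation 0.4
  theta <- diag(3)
  theta[1, 2] <- theta[2, 1] <- -0.4
  sigma <- solve(theta)
  ch <- chol(sigma)
  x <- matrix(rnorm(2000 * 3), 2000, 3) %*% ch
  ts2 <- roi_timeseries(x, tr = 2)
  net2 <- build_sic_network(ts2, lam = 0.1)
  expect_gt(net2$weights[1, 2], 0.25)
  expect_lt(abs(net2$weights[1, 2] - 0.4), 0.15)
  expect_equal(net2$weights[1, 3], 0)
  expect_equal(net2$weights[2, 3], 0)
})

test_that("kappa agrees with hand-computed binary cases and is symmetric", {
  a <- c(1, 1, 0, 0)
  expect_equal(patel_kappa(a, a), 1)
  expect_equal(patel_kappa(a, c(1, 0, 1, 0)), 0)
  # theta1 = 0.25, E = 0.25 -> kappa = 0 exactly
  b <- c(1, 0, 1, 0)
  expect_equal(patel_kappa(c(1, 1, 0, 0), b), 0)
  set.seed(5)
  for (i in 1:20) {
    u <- runif(50)
    v <- runif(50)
    expect_equal(patel_kappa(u, v), patel_kappa(v, u))
    expect_lte(abs(patel_kappa(u, v)), 1 + 1e-12)
  }
})

test_that("kappa networks have no edge threshold and bounded weights", {
  set.seed(9)
  ts <- roi_timeseries(matrix(rnorm(100 * 6), 100, 6), tr = 2)
  net <- build_kappa_network(ts)
  ut <- net$weights[upper.tri(net$weights)]
  expect_true(all(ut >= 0 & ut <= 1 + 1e-12))
  expect_identical(net$estimator, "kappa")
})

test_that("affinity/distance conversion is a reciprocal involution", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 1
  net <- weighted_network(w, c("a", "b", "c"), mode = "affinity")
  d <- to_distance_weights(net)
  expect_equal(d$weights["a", "b"], 2)
  expect_equal(d$weights["b", "c"], 1)
  expect_identical(d$weights["a", "c"], Inf)
  back <- to_affinity_weights(d)
  expect_equal(back$weights, net$weights)
  expect_error(to_distance_weights(d), "affinity")
})

test_that("all three estimators produce symmetric nonnegative zero-diagonal matrices", {
  set.seed(21)
  ts <- roi_timeseries(matrix(rnorm(300 * 8), 300, 8), tr = 2)
  for (net in list(build_corr_network(ts), build_sic_network(ts),
                   build_kappa_network(ts))) {
    expect_equal(net$weights, t(net$weights))
    expect_true(all(diag(net$weights) == 0))
    expect_true(all(net$weights >= 0))
  }
})
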