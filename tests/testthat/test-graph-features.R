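# hand-checkable fixtures
path4 <- function() {
  w <- matrix(0, 4, 4)
  for (i in 1:3) w[i, i + 1] <- w[i + 1, i] <- 1
  aff_net(w)
}
star <- function(n) {
  w <- matrix(0, n, n)
  w[1, 2:n] <- w[2:n, 1] <- 1
  aff_net(w)
}
complete <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  aff_net(w)
}

test_that("shortest-path statistics match the hand table for P4 and K_n", {
  s <- shortest_path_stats(to_distance_weights(path4()))
  # all-pairs distances of a unit path: 1,2,3,1,2,1 -> mean 10/6
  expect_equal(unname(s$summary["avg_path_length"]), 10 / 6)
  expect_equal(unname(s$summary["diameter"]), 3)
  expect_equal(unname(s$summary["radius"]), 2)
  expect_equal(unname(s$summary["connected"]), 1)

  k <- shortest_path_stats(to_distance_weights(complete(5)))
  expect_equal(unname(k$summary["diameter"]), 1)
  expect_equal(unname(k$summary["radius"]), 1)
  expect_equal(unname(k$summary["global_efficiency"]), 1)
  expect_equal(unname(k$summary["harmonic_mean_path"]), 1)
})

test_that("a cheap two-hop route beats an expensive direct edge", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 1 / 3   # direct distance 3
  s <- shortest_path_stats(to_distance_weights(aff_net(w)))
  expect_equal(s$distances[1, 3], 2)
})

test_that("clustering coefficients binarize weights and match hand counts", {
  expect_equal(unname(clustering_coefficients(complete(4))),
               c(1, 1, 1))
  expect_equal(unname(clustering_coefficients(star(5))), c(0, 0, 0))
  # 4-cycle with one diagonal: coefficients (2/3, 1, 2/3, 1) -> mean 5/6
  w <- matrix(0, 4, 4)
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(2, 4))
  w[cyc] <- w[cyc[, 2:1]] <- 0.3   # arbitrary positive weights
  cc <- clustering_coefficients(aff_net(w))
  expect_equal(unname(cc["clustering_mean"]), 5 / 6)
})

test_that("degree features and entropy follow the definition", {
  d <- degree_features(complete(4))
  expect_equal(unname(d$summary["degree_mean"]), 3)
  expect_equal(unname(d$summary["degree_entropy"]), log(4))
  s <- degree_features(star(4))
  expect_equal(unname(s$degrees), c(3, 1, 1, 1))
  # oracle: direct summation on an arbitrary weighted graph
  w <- random_affinity(5, seed = 31)
  dd <- degree_features(aff_net(w))
  p <- rowSums(w) / sum(rowSums(w))
  expect_equal(unname(dd$summary["degree_entropy"]),
               -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
})

test_that("betweenness and central point dominance reproduce Freeman's cases", {
  b <- betweenness_features(to_distance_weights(star(6)))
  expect_equal(unname(b$betweenness[1]), 1)       # center carries all pairs
  expect_equal(unname(b$summary["central_point_dominance"]), 1, tolerance = 1e-12)
  k <- betweenness_features(to_distance_weights(complete(5)))
  expect_true(all(k$betweenness == 0))
  # P4: raw pair counts (0, 2, 2, 0) -> normalized by 3
  p <- betweenness_features(to_distance_weights(path4()))
  expect_equal(unname(p$betweenness), c(0, 2 / 3, 2 / 3, 0))
})

test_that("assortativity matches the closed form for stars and the oracle", {
  expect_equal(unname(assortativity_degree_weighted(star(6))["assortativity"]),
               -1)
  reg <- assortativity_degree_weighted(complete(4))
  expect_equal(unname(reg["assortativity_degenerate"]), 1)
  w <- random_affinity(8, seed = 17)
  a <- assortativity_degree_weighted(aff_net(w))
  d <- rowSums(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  x <- c(d[idx[, 1]], d[idx[, 2]])
  y <- c(d[idx[, 2]], d[idx[, 1]])
  n <- length(x)
  r_oracle <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(unname(a["assortativity"]), r_oracle, tolerance = 1e-10)
})

test_that("effective resistance follows series/parallel rules and K_n closed form", {
  single <- matrix(0, 2, 2)
  single[1, 2] <- single[2, 1] <- 1
  expect_equal(resistance_features(aff_net(single))$resistance[1, 2], 1)
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(resistance_features(aff_net(p3))$resistance[1, 3], 2)
  tri <- resistance_features(complete(3))
  expect_equal(tri$resistance[1, 2], 2 / 3)
  expect_equal(unname(tri$summary["kirchhoff_index"]), 2)
  for (n in c(4, 7, 12, 20)) {
    kn <- resistance_features(complete(n))
    expect_equal(unname(kn$summary["kirchhoff_index"]), n - 1,
                 tolerance = 1e-8)
  }
})

test_that("Laplacian spectra: K_n closed forms, P3 by hand, disconnection", {
  for (n in c(4, 9, 20)) {
    s <- spectral_separability(complete(n))
    expect_equal(unname(s["fiedler_L"]), n, tolerance = 1e-8)
    expect_equal(unname(s["fiedler_Lnorm"]), n / (n - 1), tolerance = 1e-8)
  }
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  ev <- sort(eigen(graph_matrices(aff_net(p3))$L)$values)
  expect_equal(ev, c(0, 1, 3), tolerance = 1e-10)
  expect_equal(unname(spectral_separability(aff_net(p3))["fiedler_L"]), 1,
               tolerance = 1e-10)
  two_comp <- matrix(0, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- two_comp[3, 4] <- two_comp[4, 3] <- 1
  s <- spectral_separability(aff_net(two_comp))
  expect_equal(unname(s["fiedler_L"]), 0, tolerance = 1e-12)
})

test_that("isoperimetric estimate equals exhaustive search on symmetric fixtures", {
  # two unit triangles joined by one edge: cut 1 at |S| = 3 -> 1/3
  w <- matrix(0, 6, 6)
  tri1 <- rbind(c(1, 2), c(2, 3), c(1, 3))
  tri2 <- rbind(c(4, 5), c(5, 6), c(4, 6))
  bridge <- rbind(c(3, 4))
  for (e in list(tri1, tri2, bridge)) w[e] <- w[e[, 2:1, drop = FALSE]] <- 1
  est <- isoperimetric_estimate(aff_net(w))
  bf <- isoperimetric_bf(w)
  expect_equal(est$iso, 1 / 3)
  expect_equal(est$iso, unname(bf["iso"]))
  expect_equal(est$iso_normalized, unname(bf["nrm"]), tolerance = 1e-12)

  k4 <- isoperimetric_estimate(complete(4))
  expect_equal(k4$iso, 2)   # cut 4 at |S| = 2

  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- disc[3, 4] <- disc[4, 3] <- 1
  d_est <- isoperimetric_estimate(aff_net(disc))
  expect_equal(d_est$iso, 0)
  expect_equal(d_est$iso_normalized, 0)
})

test_that("minimum cycle basis handles trees, single cycles, and K4", {
  tree <- min_cycle_basis_features(to_distance_weights(star(5)))
  expect_equal(unname(tree), c(0, 0, 0, 0, 0))

  c5 <- matrix(0, 5, 5)
  for (i in 1:5) {
    j <- if (i == 5) 1 else i + 1
    c5[i, j] <- c5[j, i] <- 1
  }
  f <- min_cycle_basis_features(to_distance_weights(aff_net(c5)))
  expect_equal(unname(f["cycle_dimension"]), 1)
  expect_equal(unname(f["cycle_pct_nontriangle"]), 100)
  expect_equal(unname(f["cycle_max_nontriangle_len"]), 5)
  expect_equal(unname(f["cycle_total_len"]), 5)

  k4 <- min_cycle_basis_features(to_distance_weights(complete(4)))
  expect_equal(unname(k4["cycle_dimension"]), 3)   # 6 - 4 + 1
  expect_equal(unname(k4["cycle_pct_nontriangle"]), 0)
  expect_equal(unname(k4["cycle_total_len"]), 9)
})

test_that("cycle-basis dimension always equals |E| - |V| + components", {
  for (seed in 1:10) {
    w <- random_affinity(6, p_edge = 0.5, seed = seed)
    basis <- min_cycle_basis(to_distance_weights(aff_net(w)))
    m <- sum(w[upper.tri(w)] > 0)
    n_comp <- length(unique(fcdiag:::graph_components(w > 0)))
    expect_equal(basis$dimension, m - 6 + n_comp)
    expect_length(basis$cycles, basis$dimension)
  }
})

test_that("elimination fill-in matches hand eliminations", {
  # complete graph: no ordering creates fill
  for (m in c("lexicographic", "amd", "cuthill_mckee", "dulmage_mendelsohn")) {
    expect_equal(elimination_fill_in(complete(5), m)$fill_in, 0)
  }
  # 4-cycle, lexicographic: eliminating node 1 joins 2 and 4 -> 1 fill edge
  c4 <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    c4[e[1], e[2]] <- c4[e[2], e[1]] <- 1
  }
  expect_equal(elimination_fill_in(aff_net(c4), "lexicographic")$fill_in, 1)
  # star: minimum degree eliminates leaves first (no fill); center-first
  # would create choose(n-1, 2) edges
  s8 <- star(8)
  expect_equal(elimination_fill_in(s8, "amd")$fill_in, 0)
  expect_equal(fillin_bf(s8$weights, c(1, 2:8)), choose(7, 2))
  expect_error(elimination_fill_in(s8, "rainbow"), "unknown ordering")
})

test_that("sparsity grid has the 5 x 6 schema and respects thresholds", {
  w <- random_affinity(8, seed = 4) * 0.09   # all weights <= 0.1
  f <- sparsity_features(aff_net(w))
  expect_length(f, 30)
  expect_true(all(f[grepl("_t0.3", names(f), fixed = TRUE)] == 0))
  expect_true(all(f[grepl("_t0.9", names(f), fixed = TRUE)] == 0))
  # raising the threshold never increases the surviving edge count
  edges <- f[grepl("^edges_", names(f))]
  expect_true(all(diff(unname(edges)) <= 0))
  # unit-weight tree has zero fill under minimum degree at threshold 0
  tr <- star(7)
  ft <- sparsity_features(tr)
  expect_equal(unname(ft["fillin_amd_t0"]), 0)
})

test_that("edge features enumerate the upper triangle with lossless names", {
  n116 <- aff_net(matrix(0, 116, 116))
  expect_length(edge_weight_features(n116), 6670)
  f4 <- edge_weight_features(aff_net(random_affinity(4, seed = 2)))
  expect_length(f4, 6)
  labels <- roi_labels(4)
  got <- t(vapply(names(f4), parse_edge_feature, integer(2),
                  node_labels = labels))
  idx <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), ]
  expect_equal(unname(got), unname(idx))
})

test_that("the assembled feature vector is stable and isomorphism-invariant", {
  w <- random_affinity(6, seed = 8)
  f1 <- extract_all_features(aff_net(w))
  perm <- c(3, 1, 6, 2, 5, 4)
  wp <- w[perm, perm]
  f2 <- extract_all_features(aff_net(wp))
  # fill-in features depend on the node ordering and are label-dependent
  # by construction, so they are excluded from the invariance check
  global <- !grepl("_ROI[0-9]+$|^edge_|^fillin_", names(f1))
  expect_equal(f1[global], f2[global], tolerance = 1e-8)
  # per-node features: same multiset after permutation
  for (fam in c("degree", "betweenness", "resistance_eccentricity")) {
    v1 <- sort(f1[grepl(paste0("^", fam, "_ROI"), names(f1))])
    v2 <- sort(f2[grepl(paste0("^", fam, "_ROI"), names(f2))])
    expect_equal(unname(v1), unname(v2), tolerance = 1e-8)
  }
  # name schema independent of weights
  f3 <- extract_all_features(aff_net(random_affinity(6, seed = 99)))
  expect_identical(names(f1), names(f3))
})

test_that("increasing one affinity weight never decreases global efficiency", {
  set.seed(14)
  for (rep in 1:5) {
    w <- random_affinity(6, seed = rep + 40)
    eff0 <- shortest_path_stats(to_distance_weights(aff_net(w)))$summary["global_efficiency"]
    idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    pick <- idx[sample(nrow(idx), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <- w[pick[1], pick[2]] * 2
    eff1 <- shortest_path_stats(to_distance_weights(aff_net(w2)))$summary["global_efficiency"]
    expect_gte(eff1 + 1e-12, eff0)
  }
})
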