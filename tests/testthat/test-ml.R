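# small deterministic phenotype fixture
make_phenotypes <- function(n = 24, seed = 1, missing_iq = c(3, 7)) {
  set.seed(seed)
  ph <- data.frame(
    ID = sprintf("s%02d", seq_len(n)),
    Site = rep(paste0("site", 1:2), length.out = n),
    Gender = rep(c("male", "female"), each = n / 2),
    Age = round(runif(n, 7, 21), 1),
    Handedness = "right",
    VerbalIQ = round(rnorm(n, 110, 10)),
    PerformanceIQ = round(rnorm(n, 108, 10)),
    DX = rep(c("TDC", "ADHD-Combined"), length.out = n),
    stringsAsFactors = FALSE)
  ph$label <- ifelse(ph$DX == "TDC", -1L, 1L)
  ph$VerbalIQ[missing_iq] <- NA
  ph$PerformanceIQ[missing_iq] <- NA
  ph$partition <- rep(c("train", "train", "test"), length.out = n)
  ph
}

make_imaging <- function(ph, p = 6, seed = 2, constant_col = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(nrow(ph) * p), nrow(ph), p,
              dimnames = list(ph$ID, paste0("img", seq_len(p))))
  m[, 1] <- m[, 1] + ph$label   # informative column
  if (constant_col) m[, p] <- 5
  m
}

test_that("feature table: normalization, imputation, constant exclusion", {
  ph <- make_phenotypes()
  img <- make_imaging(ph)
  tab <- assemble_feature_table(ph, anatomy = img)
  expect_false("img6" %in% colnames(tab$X))          # constant dropped
  expect_true(all(c("NoIQ", "Site_site1", "Site_site2") %in%
                    colnames(tab$X)))
  # z-stats computed on the training partition
  tr <- tab$partition == "train"
  imaging_cols <- names(tab$classes)[tab$classes == "anatomical"]
  mu <- colMeans(tab$X[tr, imaging_cols])
  sdv <- apply(tab$X[tr, imaging_cols], 2, sd)
  expect_equal(unname(mu), rep(0, length(mu)), tolerance = 1e-10)
  expect_equal(unname(sdv), rep(1, length(sdv)), tolerance = 1e-10)
  # missing IQ imputed with the training mean, flagged
  miss <- ph$ID[c(3, 7)]
  expect_equal(unname(tab$X[miss, "NoIQ"]), c(1, 1))
  train_mean <- mean(ph$VerbalIQ[tr], na.rm = TRUE)
  expect_equal(unname(tab$X[miss, "VerbalIQ"]), rep(train_mean, 2))
  # global mode reproduces the whole-cohort convention
  tab_g <- assemble_feature_table(ph, anatomy = img,
                                  normalization = "global")
  expect_equal(unname(colMeans(tab_g$X[, imaging_cols])),
               rep(0, length(imaging_cols)), tolerance = 1e-10)
  expect_error(assemble_feature_table(rbind(ph, ph[1, ])),
               "duplicated subject ids")
})

test_that("fold assignment is deterministic and balanced", {
  ph <- make_phenotypes(n = 40)
  tab <- assemble_feature_table(ph, anatomy = make_imaging(ph))
  f1 <- make_folds(tab)
  f2 <- make_folds(tab)
  expect_identical(f1, f2)
  train_ids <- names(f1)
  # the round-robin deal balances every contiguous sort group: counts per
  # fold within each (site, label, gender) cell differ by at most one
  key <- paste(tab$site[train_ids], tab$labels[train_ids],
               tab$gender[train_ids])
  for (cell in unique(key)) {
    counts <- table(factor(f1[key == cell], levels = 1:2))
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_lte(abs(sum(f1 == 1) - sum(f1 == 2)), 1)
  expect_error(make_folds(tab, rows = train_ids[1], n_folds = 2),
               "fewer subjects")
})

test_that("stratification schemes partition subjects correctly", {
  ph <- make_phenotypes(n = 48)
  tab <- assemble_feature_table(ph, anatomy = make_imaging(ph, seed = 5))
  expect_identical(stratify(tab, "none")$all, ph$ID)
  by_g <- stratify(tab, "gender")
  expect_setequal(unlist(by_g), ph$ID)
  expect_length(by_g, 2)
  expect_true(all(tab$gender[by_g$male] == "male"))
  by_ga <- stratify(tab, "gender_age")
  expect_length(by_ga, 6)
  expect_setequal(unlist(by_ga), ph$ID)
  # cut-points come from training subjects only: check the binning rule
  for (g in c("male", "female")) {
    ids_g <- ph$ID[ph$Gender == g]
    cuts <- quantile(ph$Age[ph$Gender == g & ph$partition == "train"],
                     c(0.25, 0.75))
    q1 <- by_ga[[paste0(g, "_age_q1")]]
    expect_true(all(tab$age[q1] <= cuts[1]))
    q4 <- by_ga[[paste0(g, "_age_q4")]]
    expect_true(all(tab$age[q4] > cuts[2]))
  }
})

test_that("t-test ranking matches the hand-computed pooled statistic", {
  x <- cbind(f_weak = c(0.1, -0.2, 0.05, 0.12, -0.07, 0),
             f_strong = c(1, 2, 3, 4, 5, 6))
  y <- c(1, 1, 1, -1, -1, -1)
  # hand: strong feature means (2, 5), pooled var 1 -> t = -3/sqrt(2/3)
  r <- rank_ttest(x, y)
  expect_equal(r$feature[1], "f_strong")
  expect_equal(r$score[1], 3 / sqrt(2 / 3), tolerance = 1e-12)
  # permuting columns leaves the ranking content unchanged
  r2 <- rank_ttest(x[, 2:1], y)
  expect_setequal(r$feature, r2$feature)
  expect_equal(r$score[r$feature == "f_weak"],
               r2$score[r2$feature == "f_weak"])
})

test_that("RFE follows the halving schedule and keeps predictive features", {
  set.seed(8)
  n <- 40
  y <- rep(c(1, -1), n / 2)
  x <- matrix(rnorm(n * 16), n, 16,
              dimnames = list(NULL, sprintf("f%02d", 1:16)))
  x[, 3] <- y + rnorm(n, sd = 0.3)
  r <- rank_rfe(x, y)
  # 16 -> 8 (stop): two score tiers
  rounds <- floor(r$score / (max(r$score %% 1) + trunc(max(r$score))))
  expect_equal(sort(unique(trunc(r$score / (trunc(max(r$score)) + 1e-9)))),
               c(0, 1), tolerance = 1)
  expect_lte(r$rank[r$feature == "f03"], 8)
  # <= 10 features: single round, pure weight order
  r_small <- rank_rfe(x[, 1:8], y)
  m <- train_linear_classifier(x[, 1:8], y)
  expect_equal(r_small$feature,
               colnames(x[, 1:8])[order(-abs(m$weights))])
})

test_that("rank averaging and top-K selection behave as documented", {
  r1 <- fcdiag:::new_ranking(c("a", "b", "c"), c(3, 2, 1), "ttest")
  r2 <- fcdiag:::new_ranking(c("a", "b", "c"), c(3, 2, 1), "ttest")
  avg <- average_ranks(list(r1, r2))
  expect_equal(avg$feature, c("a", "b", "c"))
  # feature ranked 1st and 3rd averages 2, between 1.5 and 2.5
  r3 <- fcdiag:::new_ranking(c("a", "b", "c"), c(1, 3, 2), "ttest")
  avg2 <- average_ranks(list(r1, r3))
  ranks <- setNames(-avg2$score, avg2$feature)
  expect_equal(unname(ranks["a"]), 2)
  expect_setequal(avg2$feature, c("a", "b", "c"))
  expect_equal(select_top_k(avg, 2), c("a", "b"))
  expect_equal(select_top_k(avg, 99), c("a", "b", "c"))
  # prefix property
  expect_true(all(select_top_k(avg, 2) %in% select_top_k(avg, 3)))
  expect_error(average_ranks(list(r1, fcdiag:::new_ranking(c("a", "x"),
                                                           c(1, 2), "t"))),
               "universes")
})

test_that("the linear classifier is canonically oriented and recovers directions", {
  # 1-D separable
  x <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(-1, -1, -1, 1, 1, 1)
  m <- train_linear_classifier(x, y)
  expect_gt(m$weights[1], 0)
  expect_true(all(sign(decision_values(m, x)) == y))
  # row order must not flip the orientation
  m2 <- train_linear_classifier(x[6:1, , drop = FALSE], y[6:1])
  expect_gt(m2$weights[1], 0)

  # direction recovery on separated Gaussian blobs
  set.seed(10)
  n <- 100
  dir_true <- c(1, 2, -1) / sqrt(6)
  xx <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  yy <- ifelse(xx %*% dir_true + rnorm(n, sd = 0.2) > 0, 1, -1)
  mm <- train_linear_classifier(xx, yy)
  cosine <- sum(mm$weights * dir_true) /
    sqrt(sum(mm$weights^2) * sum(dir_true^2))
  expect_gt(cosine, 0.95)

  # duplicated feature column: weight mass splits over the copies and the
  # decision function stays essentially the same
  xd <- cbind(xx, a2 = xx[, "a"])
  md <- train_linear_classifier(xd, yy)
  expect_equal(unname(md$weights["a"] + md$weights["a2"]),
               unname(mm$weights["a"]), tolerance = 0.15)
  dv_d <- decision_values(md, xd)
  dv_s <- decision_values(mm, xx)
  expect_gt(cor(dv_d, dv_s), 0.99)
  clear <- abs(dv_s) > 0.25   # borderline points may flip either way
  expect_true(all(sign(dv_d[clear]) == sign(dv_s[clear])))
  expect_error(train_linear_classifier(xx, rep(1, n)), "both classes")
})

test_that("decision values are an aligned inner product", {
  m <- structure(list(weights = c(a = 2, b = -1), intercept = 0.5,
                      cost = 1, features = c("a", "b")),
                 class = "linear_model")
  x <- matrix(c(1, 3), 1, 2, dimnames = list("s1", c("a", "b")))
  expect_equal(unname(decision_values(m, x)), -0.5)
  # column order is irrelevant given names
  x2 <- x[, c("b", "a"), drop = FALSE]
  expect_equal(unname(decision_values(m, x2)), -0.5)
  expect_error(decision_values(m, matrix(1, 1, 1,
                                         dimnames = list(NULL, "z"))),
               "align")
})

test_that("ROC/AUC agree with concordant-pair counting", {
  expect_equal(roc_auc(c(3, 2, 1), c(1, 1, -1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 1, -1))$auc, 0)
  # hand case: scores (0.9, 0.8, 0.7, 0.6), labels (+, -, +, -) -> 3/4
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, -1, 1, -1))$auc, 3 / 4)
  # oracle: pairwise count with midrank ties on random score sets
  set.seed(12)
  for (i in 1:25) {
    y <- c(rep(1, 6), rep(-1, 8))
    s <- sample(seq(0, 1, 0.1), 14, replace = TRUE)
    pairs <- expand.grid(p = which(y == 1), n = which(y == -1))
    auc_bf <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                          ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(roc_auc(s, y)$auc, auc_bf, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("best-threshold accuracy sweeps correctly", {
  s <- c(0.9, 0.8, 0.7, 0.6)
  y <- c(1, -1, 1, -1)
  res <- accuracy_at_best_threshold(s, y, "same_set")
  expect_equal(res$accuracy, 3 / 4)
  sep <- accuracy_at_best_threshold(c(5, 4, -4, -5), c(1, 1, -1, -1),
                                    "same_set")
  expect_equal(sep$accuracy, 1)
  # all scores equal: majority-class prediction
  flat <- accuracy_at_best_threshold(rep(0, 5), c(1, 1, -1, -1, -1),
                                     "same_set")
  expect_equal(flat$accuracy, 3 / 5)
  # training-derived threshold (here 1.6, the lowest positive train score)
  # applied to evaluation scores
  tr <- accuracy_at_best_threshold(c(2, 1.4), c(1, -1), "training",
                                   train_scores = c(2, 1.6, -1, -2),
                                   train_y = c(1, 1, -1, -1))
  expect_equal(tr$accuracy, 1)
  expect_equal(tr$threshold, 1.6)
})

test_that("feature impact is weight times class mean", {
  m <- structure(list(weights = c(a = 2, b = 0), intercept = 0, cost = 1,
                      features = c("a", "b")),
                 class = "linear_model")
  x <- matrix(c(0.5, 0.7, -0.2, 1, 2, 3), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- c(1, 1, -1)
  imp <- feature_impact(m, x, y)
  expect_equal(imp$impact_adhd[imp$feature == "a"], 2 * 0.6)
  expect_equal(imp$impact_tdc[imp$feature == "a"], 2 * -0.2)
  expect_equal(imp$impact_adhd[imp$feature == "b"], 0)
})

test_that("site breakdown decomposes errors with FP + FN + accuracy = 1", {
  pred <- c(1, -1, -1, 1, 1, -1, -1, -1, -1, -1)
  truth <- c(-1, 1, 1, 1, 1, -1, -1, -1, -1, -1)
  sites <- rep("siteA", 10)
  b <- site_breakdown(pred, truth, sites)
  expect_equal(b$fp_rate, 0.1)
  expect_equal(b$fn_rate, 0.2)
  expect_equal(b$accuracy, 0.7)
  expect_equal(b$fp_rate + b$fn_rate + b$accuracy, 1)
  # counts partition the cohort
  b2 <- site_breakdown(pred, truth, rep(c("siteA", "siteB"), 5))
  expect_equal(sum(b2$n), 10)
  b3 <- site_breakdown(pred, truth, c(rep("siteA", 9), "mystery"),
                       known_sites = c("siteA", "siteB"))
  expect_true("other" %in% b3$site)
})
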