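# Feature rankings are data frames (feature, score, rank) ordered best
# first, with class "feature_ranking" and the method recorded as an
# attribute.  All ties break by position in the table's canonical column
# order, which itself is deterministic, so rankings are platform-stable.

new_ranking <- function(features, scores, method) {
  ord <- order(-scores, seq_along(features))
  out <- data.frame(feature = features[ord], score = scores[ord],
                    rank = seq_along(features), stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Rank features by two-sample t statistic
#'
#' Pooled-variance two-sample t comparing ADHD (+1) against TDC (-1) per
#' feature; features are ranked by descending `|t|`.
#'
#' @param x subjects x features numeric matrix.
#' @param y label vector (+1 / -1), both classes present.
#' @return `feature_ranking` data frame.
#' @export
rank_ttest <- function(x, y) {
  stopifnot(length(unique(y)) == 2)
  a <- x[y == 1, , drop = FALSE]
  b <- x[y == -1, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2 || n2 < 2) stop("both classes need at least 2 subjects")
  v1 <- apply(a, 2, stats::var)
  v2 <- apply(b, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t_stat <- (colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat[!is.finite(t_stat)] <- 0
  new_ranking(colnames(x), abs(t_stat), "ttest")
}

#' Rank features by single-feature nested-CV accuracy
#'
#' Each feature alone is scored by the accuracy of the linear classifier in
#' nested cross-validation: inner folds are built by the same deterministic
#' sort-and-deal rule as the outer folds, the model is trained on each
#' inner fold and evaluated on the others, and the mean accuracy is the
#' feature's score.
#'
#' @param x subjects x features matrix (rownames = subject ids).
#' @param y labels (+1 / -1) aligned with rows.
#' @param table the `feature_table` the rows come from (for the fold keys).
#' @param n_inner_folds inner fold count (default 2, matching the outer
#'   scheme).
#' @param cost SVM regularization parameter.
#' @return `feature_ranking` data frame.
#' @export
rank_nested_cv <- function(x, y, table, n_inner_folds = 2, cost = 1) {
  ids <- rownames(x)
  folds <- make_folds(table, rows = ids, n_folds = n_inner_folds)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    correct <- 0
    total <- 0
    for (f in seq_len(n_inner_folds)) {
      tr <- ids[folds[ids] == f]
      te <- setdiff(ids, tr)
      if (length(unique(y[tr])) < 2) next
      model <- train_linear_classifier(x[tr, j, drop = FALSE], y[tr],
                                       cost = cost)
      pred <- sign(decision_values(model, x[te, j, drop = FALSE]))
      pred[pred == 0] <- 1
      correct <- correct + sum(pred == y[te])
      total <- total + length(te)
    }
    if (total == 0) 0.5 else correct / total
  }, numeric(1))
  new_ranking(colnames(x), scores, "nested_cv")
}

#' Rank features by SVM recursive feature elimination
#'
#' Trains the linear classifier on all surviving features, scores them by
#' the magnitude of their weights, and eliminates the bottom half; the
#' procedure repeats until 10 or fewer features survive. A feature's final
#' score combines the last round it survived with its weight magnitude in
#' that round, so the last survivors rank highest.
#'
#' @param x subjects x features matrix.
#' @param y labels (+1 / -1).
#' @param cost SVM regularization parameter.
#' @param floor_k stop once this many or fewer features survive.
#' @return `feature_ranking` data frame.
#' @export
rank_rfe <- function(x, y, cost = 1, floor_k = 10) {
  stopifnot(ncol(x) >= 1)
  features <- colnames(x)
  surviving <- features
  round_idx <- 0
  round_of <- stats::setNames(rep(0, length(features)), features)
  weight_of <- stats::setNames(rep(0, length(features)), features)
  repeat {
    round_idx <- round_idx + 1
    model <- train_linear_classifier(x[, surviving, drop = FALSE], y,
                                     cost = cost)
    w <- abs(model$weights)
    round_of[surviving] <- round_idx
    weight_of[surviving] <- w
    m <- length(surviving)
    if (m <= floor_k) break
    n_keep <- max(ceiling(m / 2), 1)
    keep_idx <- order(-w, match(surviving, features))[seq_len(n_keep)]
    surviving <- surviving[keep_idx]
  }
  # lexicographic (round, weight) combined into one monotone score
  max_w <- max(weight_of) + 1
  scores <- round_of * max_w + weight_of
  new_ranking(features, scores[features], "rfe")
}

#' Average rankings across folds
#'
#' Mean rank position of each feature over a list of per-fold rankings on
#' the same feature universe; features are ordered by ascending average
#' rank, ties by canonical feature order of the first ranking.
#'
#' @param rankings list of `feature_ranking` data frames.
#' @return `feature_ranking` with the negative mean rank as score.
#' @export
average_ranks <- function(rankings) {
  stopifnot(length(rankings) >= 1)
  universe <- sort(rankings[[1]]$feature)
  for (r in rankings[-1]) {
    if (!identical(sort(r$feature), universe)) {
      stop("rankings cover different feature universes")
    }
  }
  mean_rank <- rowMeans(sapply(rankings, function(r) {
    stats::setNames(r$rank, r$feature)[universe]
  }))
  ord <- order(mean_rank)   # stable: ties stay in lexicographic order
  out <- data.frame(feature = universe[ord], score = -mean_rank[ord],
                    rank = seq_along(universe), stringsAsFactors = FALSE)
  attr(out, "method") <- paste0(attr(rankings[[1]], "method"), "_averaged")
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Select the top-K ranked features
#'
#' @param ranking `feature_ranking`.
#' @param k number of features (capped at the universe size; `Inf` or
#'   `"all"` selects everything).
#' @return character vector of feature names in rank order.
#' @export
select_top_k <- function(ranking, k) {
  if (identical(k, "all")) k <- Inf
  stopifnot(k >= 1)
  k <- min(k, nrow(ranking))
  ranking$feature[seq_len(k)]
}

#' Default ladder of feature-count operating points
#'
#' @param n_features total features available.
#' @return numeric vector of K values capped at `n_features` (the last
#'   entry is always `n_features`, i.e. "all").
#' @export
default_k_grid <- function(n_features) {
  grid <- c(5, 10, 20, 50, 100, 200, 400, 800, 1200, 2000, 3000, 4000, 6000)
  unique(c(grid[grid < n_features], n_features))
}
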