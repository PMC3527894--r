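#' Train the linear maximum-margin classifier
#'
#' Fits a linear SVM (hinge loss, L2 weight penalty) at fixed cost
#' `cost = 1` by default, without class reweighting or input scaling.
#' The decision function is canonicalised so that positive values always
#' point toward the ADHD (+1) class regardless of row order.
#'
#' @param x subjects x features numeric matrix (with column names).
#' @param y labels (+1 ADHD / -1 TDC); both classes must be present.
#' @param cost regularization parameter.
#' @return object of class `linear_model` with `weights` (named),
#'   `intercept`, `cost`, `features`.
#' @export
train_linear_classifier <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in the feature matrix")
  if (length(unique(y)) < 2) stop("both classes must be present")
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients the decision value toward whichever class it met first;
  # the first token of the decision-value column name is the positive class
  dv <- stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE)
  positive_class <- strsplit(colnames(attr(dv, "decision.values")),
                             "/", fixed = TRUE)[[1]][1]
  if (positive_class != "1") {
    w <- -w
    b <- -b
  }
  if (is.null(colnames(x))) names(w) <- NULL else names(w) <- colnames(x)
  structure(list(weights = w, intercept = b, cost = cost,
                 features = colnames(x)),
            class = "linear_model")
}

#' Decision values of a linear model
#'
#' `w . x + b` per subject; columns are aligned to the model's features by
#' name when both carry names.
#'
#' @param model `linear_model`.
#' @param x subjects x features matrix.
#' @return named numeric vector of scores.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "linear_model"))
  x <- as.matrix(x)
  if (!is.null(model$features)) {
    if (is.null(colnames(x)) || !all(model$features %in% colnames(x))) {
      stop("feature columns do not align with the model")
    }
    x <- x[, model$features, drop = FALSE]
  } else if (ncol(x) != length(model$weights)) {
    stop("feature columns do not align with the model")
  }
  drop(x %*% model$weights) + model$intercept
}

#' ROC curve and AUC
#'
#' Sweeps the classification threshold over the sorted unique scores and
#' reports (FPR, TPR) points; the AUC uses the Mann-Whitney midrank
#' convention, `P(score_pos > score_neg) + P(equal) / 2`, equal to the
#' trapezoidal area under the tie-aware curve.
#'
#' @param scores decision values.
#' @param y labels (+1 / -1), both classes present.
#' @return list with `auc` and a `curve` data frame (`threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, y) {
  pos <- y == 1
  neg <- y == -1
  if (!any(pos) || !any(neg)) stop("both classes must be present")
  r <- rank(scores)
  n1 <- sum(pos)
  n0 <- sum(neg)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) mean(scores[neg] >= t), 0),
    tpr = vapply(thresholds, function(t) mean(scores[pos] >= t), 0))
  list(auc = auc, curve = curve)
}

#' Accuracy at the best ROC operating point
#'
#' Chooses the score threshold maximising the percent correct, either on
#' the evaluation scores themselves (`"same_set"`) or on a separate
#' training score set (`"training"`, the default when training scores are
#' given), and applies it to the evaluation scores.
#'
#' @param scores evaluation decision values.
#' @param y evaluation labels.
#' @param threshold_source `"same_set"` or `"training"`.
#' @param train_scores,train_y threshold-selection set (required for
#'   `"training"`).
#' @return list with `accuracy` and the chosen `threshold`.
#' @export
accuracy_at_best_threshold <- function(scores, y,
                                       threshold_source = c("same_set",
                                                            "training"),
                                       train_scores = NULL,
                                       train_y = NULL) {
  threshold_source <- match.arg(threshold_source)
  if (threshold_source == "training") {
    if (is.null(train_scores) || is.null(train_y)) {
      stop("training threshold source needs train_scores and train_y")
    }
    src_s <- train_scores
    src_y <- train_y
  } else {
    src_s <- scores
    src_y <- y
  }
  if (length(unique(src_y)) < 2) stop("threshold source needs both classes")
  cand <- c(-Inf, sort(unique(src_s)), Inf)
  acc_at <- function(t, s, yy) mean(ifelse(s >= t, 1, -1) == yy)
  best <- cand[which.max(vapply(cand, acc_at, 0, s = src_s, yy = src_y))]
  list(accuracy = acc_at(best, scores, y), threshold = best)
}

#' Per-class feature impact
#'
#' The impact of a feature on a class is the learned weight times the mean
#' value the feature takes within that class: a positive ADHD impact drives
#' decisions toward the ADHD diagnosis, a negative TDC impact likewise
#' favours the control label (whose decision side is negative).
#'
#' @param model `linear_model`.
#' @param x subjects x features matrix.
#' @param y labels (+1 / -1).
#' @return data frame (feature, impact_adhd, impact_tdc) in model feature
#'   order.
#' @export
feature_impact <- function(model, x, y) {
  stopifnot(inherits(model, "linear_model"))
  x <- as.matrix(x)[, model$features, drop = FALSE]
  mu_adhd <- colMeans(x[y == 1, , drop = FALSE])
  mu_tdc <- colMeans(x[y == -1, , drop = FALSE])
  data.frame(feature = model$features,
             impact_adhd = unname(model$weights * mu_adhd),
             impact_tdc = unname(model$weights * mu_tdc),
             stringsAsFactors = FALSE)
}

#' Per-site error decomposition
#'
#' For each acquisition site: false-positive rate (predicted ADHD among
#' true TDC, over the site's total), false-negative rate (analogous), and
#' accuracy, so that `FP + FN + accuracy = 1` per site.
#'
#' @param predictions predicted labels (+1 / -1).
#' @param labels true labels.
#' @param sites site id per subject (unknown ids grouped under "other").
#' @param known_sites optional vector of expected site ids.
#' @return data frame (site, n, fp_rate, fn_rate, accuracy).
#' @export
site_breakdown <- function(predictions, labels, sites, known_sites = NULL) {
  stopifnot(length(predictions) == length(labels),
            length(labels) == length(sites))
  sites <- as.character(sites)
  if (!is.null(known_sites)) sites[!sites %in% known_sites] <- "other"
  out <- lapply(sort(unique(sites)), function(s) {
    idx <- sites == s
    n <- sum(idx)
    fp <- sum(predictions[idx] == 1 & labels[idx] == -1) / n
    fn <- sum(predictions[idx] == -1 & labels[idx] == 1) / n
    data.frame(site = s, n = n, fp_rate = fp, fn_rate = fn,
               accuracy = 1 - fp - fn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
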