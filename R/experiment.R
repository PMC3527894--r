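#' Build per-subject feature matrices from a synthetic cohort
#'
#' Runs the chosen network estimator on every subject's time series,
#' extracts the full graph-feature battery, and assembles the anatomical
#' feature vectors, yielding the matrices [assemble_feature_table()] takes.
#'
#' @param cohort `synthetic_cohort`.
#' @param estimator `"corr"`, `"sic"`, or `"kappa"`.
#' @param fdr_q FDR rate for the correlation estimator.
#' @param lam penalty for the sparse inverse-covariance estimator.
#' @return list with `network` and `anatomy` matrices (rownames = subject
#'   ids).
#' @export
cohort_feature_matrices <- function(cohort, estimator = c("corr", "sic",
                                                          "kappa"),
                                    fdr_q = 0.01, lam = 0.1) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- cohort$phenotypes$ID
  build <- switch(estimator,
                  corr = function(ts) build_corr_network(ts, q = fdr_q),
                  sic = function(ts) build_sic_network(ts, lam = lam),
                  kappa = build_kappa_network)
  net_rows <- lapply(ids, function(id) {
    extract_all_features(build(cohort$timeseries[[id]]))
  })
  network <- do.call(rbind, net_rows)
  rownames(network) <- ids
  anat_rows <- lapply(ids, function(id) {
    assemble_anatomical_features(cohort$anatomy$records[[id]])
  })
  anatomy <- do.call(rbind, anat_rows)
  rownames(anatomy) <- ids
  list(network = network, anatomy = anatomy)
}

#' Experiment configuration
#'
#' @param methods ranking methods to run.
#' @param k_grid feature-count ladder (default: the standard ladder capped
#'   at the feature-universe size).
#' @param strata stratification scheme (see [stratify()]).
#' @param n_folds cross-validation folds (default 2).
#' @param cost SVM regularization parameter.
#' @param report_method,report_k the cell used for ROC curves, impacts, and
#'   the site/subtype breakdowns (defaults: first method, largest K).
#' @param threshold_source threshold rule for test accuracy
#'   (`"training"` or `"same_set"`).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(methods = c("ttest", "nested_cv", "rfe"),
                              k_grid = NULL,
                              strata = "gender",
                              n_folds = 2,
                              cost = 1,
                              report_method = methods[1],
                              report_k = NULL,
                              threshold_source = "training") {
  structure(list(methods = methods, k_grid = k_grid, strata = strata,
                 n_folds = n_folds, cost = cost,
                 report_method = report_method, report_k = report_k,
                 threshold_source = threshold_source),
            class = "experiment_config")
}

rank_with_method <- function(method, x, y, table, cost) {
  switch(method,
         ttest = rank_ttest(x, y),
         nested_cv = rank_nested_cv(x, y, table, cost = cost),
         rfe = rank_rfe(x, y, cost = cost),
         stop(sprintf("unknown ranking method '%s'", method)))
}

# Core stratified engine.  `train_labels` lets a permutation run override
# the labels used for selection and training; evaluation always uses the
# table's true labels.  Returns pooled decision values and final models.
run_stratified <- function(table, config, train_labels = table$labels) {
  strata <- stratify(table, config$strata)
  ids_all <- rownames(table$X)
  k_grid <- config$k_grid
  if (is.null(k_grid)) k_grid <- default_k_grid(ncol(table$X))
  k_grid <- sort(unique(pmin(k_grid, ncol(table$X))))

  cells <- expand.grid(method = config$methods, k = k_grid,
                       stringsAsFactors = FALSE)
  cv_scores <- lapply(seq_len(nrow(cells)), function(i) numeric(0))
  test_scores <- cv_scores
  train_scores <- cv_scores
  final_models <- list()

  for (s_name in names(strata)) {
    s_ids <- strata[[s_name]]
    tr_ids <- s_ids[table$partition[s_ids] == "train"]
    te_ids <- s_ids[table$partition[s_ids] == "test"]
    if (length(unique(train_labels[tr_ids])) < 2) {
      stop(sprintf("stratum '%s' does not contain both classes in training",
                   s_name))
    }
    folds <- make_folds(table, rows = tr_ids, n_folds = config$n_folds)
    x <- table$X

    per_fold_rankings <- list()
    for (m in config$methods) {
      per_fold_rankings[[m]] <- lapply(seq_len(config$n_folds), function(f) {
        rows <- tr_ids[folds[tr_ids] == f]
        rank_with_method(m, x[rows, , drop = FALSE], train_labels[rows],
                         table, config$cost)
      })
    }

    for (i in seq_len(nrow(cells))) {
      m <- cells$method[i]
      k <- cells$k[i]
      # cross-validation: train inside each fold with its own ranking,
      # score the held-out subjects
      for (f in seq_len(config$n_folds)) {
        rows <- tr_ids[folds[tr_ids] == f]
        held <- setdiff(tr_ids, rows)
        feats <- select_top_k(per_fold_rankings[[m]][[f]], k)
        model <- train_linear_classifier(x[rows, feats, drop = FALSE],
                                         train_labels[rows], config$cost)
        sc <- decision_values(model, x[held, feats, drop = FALSE])
        cv_scores[[i]] <- c(cv_scores[[i]], sc)
      }
      # test: average ranks across folds, train on the whole training part
      avg <- average_ranks(per_fold_rankings[[m]])
      feats <- select_top_k(avg, k)
      model <- train_linear_classifier(x[tr_ids, feats, drop = FALSE],
                                       train_labels[tr_ids], config$cost)
      train_scores[[i]] <- c(train_scores[[i]],
                             decision_values(model, x[tr_ids, feats,
                                                      drop = FALSE]))
      if (length(te_ids) > 0) {
        test_scores[[i]] <- c(test_scores[[i]],
                              decision_values(model, x[te_ids, feats,
                                                       drop = FALSE]))
      }
      if (m == config$report_method &&
          k == max(k_grid[k_grid <= resolve_report_k(config, k_grid)])) {
        final_models[[s_name]] <- model
      }
    }
  }
  list(cells = cells, cv_scores = cv_scores, test_scores = test_scores,
       train_scores = train_scores, final_models = final_models,
       k_grid = k_grid)
}

resolve_report_k <- function(config, k_grid) {
  if (is.null(config$report_k)) max(k_grid) else config$report_k
}

# with 2-fold CV each subject is scored once; scores are named by subject
pooled_eval <- function(scores, labels) {
  y <- labels[names(scores)]
  roc_auc(scores, y)
}

#' Run the full stratified classification experiment
#'
#' Executes the complete evaluation design on an assembled feature table:
#' per-stratum two-fold cross-validation with per-fold feature rankings for
#' every method, rank averaging, top-K selection over the configured
#' ladder, linear-SVM training, and pooling of decision values across
#' strata before any ROC is computed. The AUC/accuracy grids cover
#' (method x K x split); the report cell additionally yields ROC curves,
#' feature impacts per stratum, and site/subtype breakdowns on the test
#' partition. Everything is deterministic given the table and
#' configuration.
#'
#' @param table `feature_table` whose `partition` column marks training and
#'   test subjects.
#' @param config `experiment_config`.
#' @return object of class `experiment_result` with elements `grid`,
#'   `roc`, `impacts`, `site`, `subtype`, `models`, `config`.
#' @export
run_full_experiment <- function(table, config = experiment_config()) {
  stopifnot(inherits(table, "feature_table"))
  run <- run_stratified(table, config)
  cells <- run$cells
  labels <- table$labels
  have_test <- any(table$partition == "test")

  grid <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cv <- pooled_eval(run$cv_scores[[i]], labels)
    acc_cv <- accuracy_at_best_threshold(run$cv_scores[[i]],
                                         labels[names(run$cv_scores[[i]])],
                                         "same_set")$accuracy
    if (have_test) {
      te <- pooled_eval(run$test_scores[[i]], labels)
      tr_s <- run$train_scores[[i]]
      acc_te <- if (config$threshold_source == "training") {
        accuracy_at_best_threshold(run$test_scores[[i]],
                                   labels[names(run$test_scores[[i]])],
                                   "training", train_scores = tr_s,
                                   train_y = labels[names(tr_s)])$accuracy
      } else {
        accuracy_at_best_threshold(run$test_scores[[i]],
                                   labels[names(run$test_scores[[i]])],
                                   "same_set")$accuracy
      }
      data.frame(method = cells$method[i], k = cells$k[i],
                 auc_cv = cv$auc, accuracy_cv = acc_cv,
                 auc_test = te$auc, accuracy_test = acc_te,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = cells$method[i], k = cells$k[i],
                 auc_cv = cv$auc, accuracy_cv = acc_cv,
                 auc_test = NA_real_, accuracy_test = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))

  report_k <- max(run$k_grid[run$k_grid <=
                               resolve_report_k(config, run$k_grid)])
  ri <- which(cells$method == config$report_method & cells$k == report_k)
  roc <- list(cv = pooled_eval(run$cv_scores[[ri]], labels)$curve)
  impacts <- lapply(run$final_models, function(model) {
    rows <- names(labels)[table$partition == "train"]
    rows <- rows[rows %in% rownames(table$X)]
    feature_impact(model, table$X[rows, , drop = FALSE], labels[rows])
  })
  site <- NULL
  subtype <- NULL
  if (have_test) {
    roc$test <- pooled_eval(run$test_scores[[ri]], labels)$curve
    te_s <- run$test_scores[[ri]]
    tr_s <- run$train_scores[[ri]]
    thr <- accuracy_at_best_threshold(tr_s, labels[names(tr_s)],
                                      "same_set")$threshold
    pred <- ifelse(te_s >= thr, 1, -1)
    site <- site_breakdown(pred, labels[names(te_s)],
                           table$site[names(te_s)])
    subtype <- subtype_auc(te_s, table$dx[names(te_s)])
  }
  structure(list(grid = grid, roc = roc, impacts = impacts, site = site,
                 subtype = subtype, models = run$final_models,
                 config = config, k_grid = run$k_grid),
            class = "experiment_result")
}

# AUC of each ADHD subtype against the same controls, from pooled test
# decision values
subtype_auc <- function(scores, dx) {
  out <- list()
  for (st in setdiff(sort(unique(dx)), "TDC")) {
    sel <- dx %in% c(st, "TDC")
    y <- ifelse(dx[sel] == "TDC", -1, 1)
    if (length(unique(y)) < 2 || sum(y == 1) < 2) next
    out[[st]] <- roc_auc(scores[sel], y)$auc
  }
  if (length(out) == 0) return(NULL)
  data.frame(subtype = names(out), auc = unlist(out),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation test of a classification cell
#'
#' Re-runs feature selection, training, and evaluation `n_perm` times with
#' the training labels shuffled within each (stratum, fold) group — so the
#' class balance of every fold and the stratification approach are
#' preserved — and reports the mean AUC and accuracy under the null, the
#' SD of the estimate of each mean, and the SD of the permutation
#' distributions themselves.
#'
#' @param table `feature_table`.
#' @param config `experiment_config`; only the report cell (one method and
#'   one K) is evaluated per permutation.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed for the label shuffles.
#' @param split evaluate on `"test"` or `"cv"` decision values.
#' @return list with `mean_auc`, `sd_mean_auc`, `sd_auc`, `mean_accuracy`,
#'   `sd_mean_accuracy`, `sd_accuracy`, and the per-permutation `auc` and
#'   `accuracy` vectors.
#' @export
permutation_test <- function(table, config = experiment_config(),
                             n_perm = 100, seed = 1,
                             split = c("test", "cv")) {
  split <- match.arg(split)
  stopifnot(n_perm >= 2)
  report_k <- resolve_report_k(config, default_k_grid(ncol(table$X)))
  one_cell <- config
  one_cell$methods <- config$report_method
  one_cell$k_grid <- report_k

  strata <- stratify(table, config$strata)
  groups <- list()
  for (s_name in names(strata)) {
    s_ids <- strata[[s_name]]
    tr_ids <- s_ids[table$partition[s_ids] == "train"]
    folds <- make_folds(table, rows = tr_ids, n_folds = config$n_folds)
    for (f in seq_len(config$n_folds)) {
      groups[[paste(s_name, f)]] <- tr_ids[folds[tr_ids] == f]
    }
  }
  labels <- table$labels
  aucs <- numeric(n_perm)
  accs <- numeric(n_perm)
  with_substream(seed, 6, {
    for (p in seq_len(n_perm)) {
      perm_labels <- labels
      for (g in groups) {
        perm_labels[g] <- labels[g][sample.int(length(g))]
      }
      run <- run_stratified(table, one_cell, train_labels = perm_labels)
      sc <- if (split == "test") run$test_scores[[1]] else run$cv_scores[[1]]
      y <- labels[names(sc)]
      aucs[p] <- roc_auc(sc, y)$auc
      accs[p] <- accuracy_at_best_threshold(sc, y, "same_set")$accuracy
    }
  })
  list(mean_auc = mean(aucs), sd_mean_auc = stats::sd(aucs) / sqrt(n_perm),
       sd_auc = stats::sd(aucs),
       mean_accuracy = mean(accs),
       sd_mean_accuracy = stats::sd(accs) / sqrt(n_perm),
       sd_accuracy = stats::sd(accs),
       auc = aucs, accuracy = accs)
}
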