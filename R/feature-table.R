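#' Assemble the subjects x features classification table
#'
#' Joins phenotype, anatomical, and network feature blocks into one matrix
#' with per-feature class tags. Imaging features (anatomical + network) are
#' z-normalised; phenotype features are used raw. Missing Verbal or
#' Performance IQ is imputed with the mean IQ of the normalisation cohort
#' and flagged by a binary `NoIQ` feature; one-hot site indicators are
#' added. Columns constant across the whole cohort (or across the
#' normalisation cohort, whose SD would be 0) are dropped.
#'
#' The normalisation cohort is the training partition by default (no
#' leakage of test statistics); `normalization = "global"` reproduces the
#' classical whole-dataset convention.
#'
#' @param phenotypes phenotype data frame with columns `ID`, `Site`,
#'   `Gender`, `Age`, `Handedness`, `VerbalIQ`, `PerformanceIQ`, `DX`,
#'   `label`, and optionally `partition` (defaults to all-train).
#' @param anatomy optional subjects x features numeric matrix (rownames =
#'   subject IDs) of anatomical features.
#' @param network optional subjects x features numeric matrix of network
#'   features.
#' @param classes feature classes to include.
#' @param normalization `"training"` or `"global"`.
#' @return object of class `feature_table`: list with the feature matrix
#'   `X`, per-feature `classes`, `labels` (+1 ADHD / -1 TDC), and subject
#'   metadata columns.
#' @export
assemble_feature_table <- function(phenotypes, anatomy = NULL, network = NULL,
                                   classes = c("phenotype", "anatomical",
                                               "network"),
                                   normalization = c("training", "global")) {
  normalization <- match.arg(normalization)
  classes <- match.arg(classes, several.ok = TRUE)
  ids <- phenotypes$ID
  if (anyDuplicated(ids)) stop("duplicated subject ids")
  if (is.null(phenotypes$partition)) phenotypes$partition <- "train"
  norm_rows <- if (normalization == "training") {
    phenotypes$partition == "train"
  } else rep(TRUE, length(ids))

  blocks <- list()
  tags <- character(0)
  if ("phenotype" %in% classes) {
    hand_code <- function(h) {
      if (is.numeric(h)) return(h)   # continuous laterality scores pass through
      unname(c(right = 1, left = 2, ambidextrous = 3)[as.character(h)])
    }
    viq <- phenotypes$VerbalIQ
    piq <- phenotypes$PerformanceIQ
    noiq <- as.numeric(is.na(viq) & is.na(piq))
    viq[is.na(viq)] <- mean(viq[norm_rows], na.rm = TRUE)
    piq[is.na(piq)] <- mean(piq[norm_rows], na.rm = TRUE)
    sites <- sort(unique(phenotypes$Site))
    site_onehot <- sapply(sites, function(s) as.numeric(phenotypes$Site == s))
    colnames(site_onehot) <- paste0("Site_", sites)
    ph <- cbind(Age = phenotypes$Age,
                Handedness = hand_code(phenotypes$Handedness),
                VerbalIQ = viq, PerformanceIQ = piq, NoIQ = noiq,
                site_onehot)
    rownames(ph) <- ids
    blocks$phenotype <- ph
    tags <- c(tags, rep("phenotype", ncol(ph)))
  }
  add_imaging <- function(mat, tag) {
    if (is.null(mat)) return()
    mat <- as.matrix(mat)
    if (!all(ids %in% rownames(mat))) {
      stop(sprintf("%s features missing for some subjects", tag))
    }
    mat <- mat[ids, , drop = FALSE]
    mu <- colMeans(mat[norm_rows, , drop = FALSE])
    sdev <- apply(mat[norm_rows, , drop = FALSE], 2, stats::sd)
    keep <- sdev > 0 & apply(mat, 2, function(col) stats::sd(col) > 0)
    mat <- sweep(sweep(mat[, keep, drop = FALSE], 2, mu[keep]), 2,
                 sdev[keep], `/`)
    blocks[[tag]] <<- mat
    tags <<- c(tags, rep(tag, ncol(mat)))
  }
  if ("anatomical" %in% classes) add_imaging(anatomy, "anatomical")
  if ("network" %in% classes) add_imaging(network, "network")

  x <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(x))) stop("duplicated feature names across blocks")
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  x <- x[, keep, drop = FALSE]
  tags <- tags[keep]
  structure(
    list(X = x,
         classes = stats::setNames(tags, colnames(x)),
         labels = stats::setNames(phenotypes$label, ids),
         site = stats::setNames(phenotypes$Site, ids),
         gender = stats::setNames(phenotypes$Gender, ids),
         age = stats::setNames(phenotypes$Age, ids),
         dx = stats::setNames(phenotypes$DX, ids),
         partition = stats::setNames(phenotypes$partition, ids),
         normalization = normalization),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s: %d", names(table(x$classes)),
                            table(x$classes)), collapse = ", ")))
  invisible(x)
}

#' Deterministic balanced fold assignment
#'
#' Sorts subjects lexicographically by (site, label, gender, age, id) and
#' deals them round-robin into `n_folds` folds, so per-fold proportions of
#' each sort key differ by at most one subject from the overall cohort.
#'
#' @param table `feature_table`.
#' @param rows subject ids (or logical/integer index) to fold; defaults to
#'   the training partition.
#' @param n_folds number of folds (default 2).
#' @return named integer vector of fold ids.
#' @export
make_folds <- function(table, rows = NULL, n_folds = 2) {
  stopifnot(inherits(table, "feature_table"), n_folds >= 2)
  ids <- rownames(table$X)
  if (is.null(rows)) rows <- ids[table$partition == "train"]
  if (!is.character(rows)) rows <- ids[rows]
  if (length(rows) < n_folds) stop("fewer subjects than folds")
  ord <- rows[order(table$site[rows], table$labels[rows],
                    table$gender[rows], table$age[rows], rows)]
  folds <- rep(seq_len(n_folds), length.out = length(ord))
  stats::setNames(folds, ord)[rows]
}

#' Partition subjects into classifier strata
#'
#' `"none"` keeps one stratum; `"gender"` splits by gender; `"gender_age"`
#' further splits each gender at the 25th and 75th age percentiles, giving
#' six strata. Age cut-points are computed on the training subjects within
#' each gender and reused to bin test subjects. Downstream results are
#' pooled across strata before evaluation.
#'
#' @param table `feature_table`.
#' @param scheme `"none"`, `"gender"`, or `"gender_age"`.
#' @return named list of subject-id vectors (one per stratum).
#' @export
stratify <- function(table, scheme = c("none", "gender", "gender_age")) {
  scheme <- match.arg(scheme)
  ids <- rownames(table$X)
  if (scheme == "none") return(list(all = ids))
  out <- list()
  for (g in sort(unique(table$gender))) {
    g_ids <- ids[table$gender[ids] == g]
    if (length(g_ids) == 0) next
    if (scheme == "gender") {
      out[[g]] <- g_ids
    } else {
      train_ages <- table$age[g_ids][table$partition[g_ids] == "train"]
      if (length(train_ages) == 0) {
        stop(sprintf("stratum '%s' has no training subjects", g))
      }
      cuts <- stats::quantile(train_ages, c(0.25, 0.75), names = FALSE,
                              type = 7)
      bin <- cut(table$age[g_ids], c(-Inf, cuts, Inf),
                 labels = c("age_q1", "age_q2q3", "age_q4"))
      for (b in levels(bin)) {
        key <- paste(g, b, sep = "_")
        members <- g_ids[bin == b]
        if (length(members) == 0) stop(sprintf("empty stratum '%s'", key))
        out[[key]] <- members
      }
    }
  }
  out
}
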