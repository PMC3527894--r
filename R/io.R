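# Plain-text on-disk formats: TSV for time series and feature tables, CSV
# for phenotypes and adjacency matrices, JSON for ground truth and run
# manifests.  Numeric precision is fixed at 12 significant digits for
# round-trip stability.

fmt_num <- function(x) sprintf("%.12g", x)

#' Write / read a region time-series TSV
#'
#' One row per timepoint, one labelled column per region; the TR and ids
#' are carried in `#`-prefixed header comment lines.
#'
#' @param ts `roi_timeseries`.
#' @param path file path.
#' @return `write_timeseries` returns `path` invisibly; `read_timeseries`
#'   returns the `roi_timeseries`.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tr=%s", fmt_num(ts$tr)),
               sprintf("# subject=%s session=%s", ts$subject_id,
                       ts$session_id),
               paste(ts$region_labels, collapse = "\t")), con)
  utils::write.table(matrix(fmt_num(ts$values), nrow = nrow(ts$values)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) stop("missing header or data rows")
  tr <- 2
  subject <- "subject"; session <- "1"
  for (m in meta) {
    if (grepl("tr=", m)) {
      tr <- as.numeric(sub("^.*tr=([-+0-9.eE]+).*$", "\\1", m))
    }
    if (grepl("subject=", m)) {
      subject <- sub(".*subject=(\\S+).*", "\\1", m)
      session <- sub(".*session=(\\S+).*", "\\1", m)
    }
  }
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (any(!is.na(suppressWarnings(as.numeric(labels))))) {
    stop("missing header row of region labels")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad_len <- which(lengths(rows) != length(labels))
  if (length(bad_len) > 0) {
    stop(sprintf("ragged row at line %d", bad_len[1] + length(meta) + 1))
  }
  vals <- suppressWarnings(vapply(rows, as.numeric,
                                  numeric(length(labels))))
  vals <- t(matrix(vals, nrow = length(labels)))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("non-numeric cell at line %d", bad + length(meta) + 1))
  }
  roi_timeseries(vals, labels, tr = tr, subject_id = subject,
                 session_id = session)
}

#' Read an ADHD-200-style phenotype CSV
#'
#' Expects columns `ID`, `Site`, `Gender`, `Age`, `Handedness`, `VerbalIQ`,
#' `PerformanceIQ`, `DX` (extra columns pass through). Empty IQ cells
#' become explicit `NA`s; handedness may be categorical codes or continuous
#' laterality scores. Diagnosis strings must be TDC or a recognised ADHD
#' subtype.
#'
#' @param path file path.
#' @return typed phenotype data frame with the binary `label` column added.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ID", "Site", "Gender", "Age", "Handedness", "VerbalIQ",
                "PerformanceIQ", "DX")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols) > 0) {
    stop(sprintf("phenotype file lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(ph$ID)) stop("duplicate subject id in phenotype file")
  known_dx <- c("TDC", "ADHD-Combined", "ADHD-Inattentive",
                "ADHD-Hyperactive")
  bad <- setdiff(unique(ph$DX), known_dx)
  if (length(bad) > 0) {
    stop(sprintf("unknown diagnosis code: %s", paste(bad, collapse = ", ")))
  }
  ph$VerbalIQ <- as.numeric(ph$VerbalIQ)
  ph$PerformanceIQ <- as.numeric(ph$PerformanceIQ)
  ph$Age <- as.numeric(ph$Age)
  num_hand <- suppressWarnings(as.numeric(ph$Handedness))
  if (!anyNA(num_hand)) ph$Handedness <- num_hand
  if (is.null(ph$label)) ph$label <- ifelse(ph$DX == "TDC", -1L, 1L)
  ph
}

#' Write a phenotype table
#' @param phenotypes phenotype data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write / read a weighted network
#'
#' Two layouts: a dense adjacency CSV with a label header row/column, or an
#' edge-list TSV `(node_i, node_j, weight, signed_value)`. The weight mode
#' and estimator are stored in `#` comment lines. Reading canonicalises:
#' the matrix is symmetrised by averaging (within 1e-9) and the diagonal
#' zeroed; in an edge list, absent pairs are weight 0 (affinity) or `Inf`
#' (distance).
#'
#' @param net `weighted_network`.
#' @param path file path.
#' @param layout `"adjacency"` or `"edgelist"`.
#' @return `write_network` returns `path`; `read_network` the network.
#' @export
write_network <- function(net, path, layout = c("adjacency", "edgelist")) {
  layout <- match.arg(layout)
  stopifnot(inherits(net, "weighted_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s estimator=%s layout=%s", net$mode,
                     net$estimator, layout), con)
  if (layout == "adjacency") {
    writeLines(paste(c("node", net$node_labels), collapse = ","), con)
    for (i in seq_along(net$node_labels)) {
      writeLines(paste(c(net$node_labels[i], fmt_num(net$weights[i, ])),
                       collapse = ","), con)
    }
  } else {
    writeLines("node_i\tnode_j\tweight\tsigned", con)
    idx <- which(upper.tri(net$weights), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    present <- if (net$mode == "affinity") {
      net$weights[idx] > 0
    } else is.finite(net$weights[idx])
    idx <- idx[present, , drop = FALSE]
    signed <- if (is.null(net$signed)) net$weights[idx] else net$signed[idx]
    for (r in seq_len(nrow(idx))) {
      writeLines(paste(c(net$node_labels[idx[r, 1]],
                         net$node_labels[idx[r, 2]],
                         fmt_num(net$weights[idx[r, , drop = FALSE]]),
                         fmt_num(signed[r])), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_network
#' @param node_labels required when reading an edge list (defines the node
#'   universe and canonical order).
#' @export
read_network <- function(path, node_labels = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  mode <- if (any(grepl("mode=distance", meta))) "distance" else "affinity"
  estimator <- sub(".*estimator=(\\S+).*", "\\1",
                   meta[grepl("estimator=", meta)][1])
  if (is.na(estimator)) estimator <- "manual"
  layout <- if (any(grepl("layout=edgelist", meta))) "edgelist" else "adjacency"
  body <- lines[!startsWith(lines, "#")]
  if (layout == "adjacency") {
    header <- strsplit(body[1], ",", fixed = TRUE)[[1]][-1]
    cells <- strsplit(body[-1], ",", fixed = TRUE)
    w <- t(vapply(cells, function(row) as.numeric(row[-1]),
                  numeric(length(header))))
    if (max(abs(w - t(w)), na.rm = TRUE) > 1e-9) {
      stop("adjacency matrix asymmetric beyond tolerance")
    }
    w <- (w + t(w)) / 2
    diag(w) <- 0
    if (mode == "affinity" && any(w[is.finite(w)] < 0)) {
      stop("negative weight in network file (affinities are magnitudes)")
    }
    weighted_network(w, header, mode = mode, estimator = estimator)
  } else {
    if (is.null(node_labels)) stop("edge-list layout needs node_labels")
    n <- length(node_labels)
    w <- matrix(if (mode == "affinity") 0 else Inf, n, n)
    diag(w) <- 0
    sg <- matrix(0, n, n)
    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    for (r in rows) {
      i <- match(r[1], node_labels)
      j <- match(r[2], node_labels)
      if (is.na(i) || is.na(j)) stop("edge references unknown node label")
      val <- as.numeric(r[3])
      if (mode == "affinity" && val < 0) {
        stop("negative weight in network file (affinities are magnitudes)")
      }
      w[i, j] <- w[j, i] <- val
      sg[i, j] <- sg[j, i] <- as.numeric(r[4])
    }
    weighted_network(w, node_labels, mode = mode, estimator = estimator,
                     signed = sg)
  }
}

#' Write a synthetic cohort to standard files
#'
#' Per-subject time-series TSVs under `timeseries/`, a phenotype CSV, one
#' anatomy TSV (subjects x features), and the ground truth as JSON.
#'
#' @param cohort `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir` invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(cohort$timeseries)) {
    write_timeseries(cohort$timeseries[[id]],
                     file.path(out_dir, "timeseries", paste0(id, ".tsv")))
  }
  write_phenotypes(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"))
  anat <- do.call(rbind, lapply(cohort$anatomy$records,
                                assemble_anatomical_features))
  rownames(anat) <- names(cohort$anatomy$records)
  utils::write.table(data.frame(ID = rownames(anat), anat,
                                check.names = FALSE),
                     file.path(out_dir, "anatomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- cohort$truth
    jsonlite::write_json(
      list(effect_edges = truth$effect_edges,
           effect_vertices = truth$effect_vertices,
           effect_magnitude = truth$effect_magnitude,
           group_labels = as.list(truth$group_labels)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(out_dir)
}
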