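#' Synthetic-cohort configuration
#'
#' Parameters of the generative model for a complete synthetic cohort:
#' band-limited correlated Gaussian ROI signals with group-specific sparse
#' precision structure, multi-site offsets, gender-dependent diagnosis
#' prevalence, group shifts in IQ and in a subset of thickness features, and
#' missing IQ values. Defaults mirror the printed cohort structure of the
#' public multi-site ADHD release: ages uniform on 7-21 years, 8 sites,
#' roughly 53% male overall prevalence near 36%.
#'
#' @param n_subjects_per_gender subjects per gender (named or unnamed pair;
#'   a single number is used for both).
#' @param adhd_prevalence_by_gender probability of an ADHD diagnosis for
#'   `c(male, female)`.
#' @param n_sites number of acquisition sites.
#' @param site_effect_sd SD of the additive per-site offset applied to
#'   time-series amplitude and anatomical means (signal units / mm).
#' @param n_regions atlas regions (network nodes).
#' @param n_timepoints timepoints per subject.
#' @param tr repetition time, seconds.
#' @param band band-pass edges in Hz; must lie inside `(0, 1/(2 tr))`.
#' @param n_effect_edges number of precision entries differing between
#'   diagnostic groups.
#' @param effect_magnitude partial-correlation difference planted on each
#'   effect edge.
#' @param icosphere_level subdivision level of the thickness grid.
#' @param n_effect_vertices thickness vertices carrying a group shift.
#' @param thickness_effect group thickness shift in mm (TDC minus ADHD).
#' @param thickness_sd between-subject thickness SD at a vertex, mm.
#' @param female_effect_scale multiplier applied to the planted edge and
#'   thickness effects in girls, making the effect pattern gender-dependent
#'   (1 = identical effects in both genders).
#' @param iq_shift IQ-point deficit of the ADHD group (TDC minus ADHD).
#' @param iq_missing_rate probability that a subject's IQ scores are missing.
#' @param left_handed_rate probability of left-handedness.
#' @param test_fraction fraction of subjects held out as the test partition.
#' @param seed integer seed making the whole cohort reproducible.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_gender = c(male = 40, female = 40),
                          adhd_prevalence_by_gender = c(male = 0.45, female = 0.25),
                          n_sites = 8,
                          site_effect_sd = 0.1,
                          n_regions = 116,
                          n_timepoints = 250,
                          tr = 2,
                          band = c(0.009, 0.08),
                          n_effect_edges = 8,
                          effect_magnitude = 0.15,
                          icosphere_level = 1,
                          n_effect_vertices = 30,
                          thickness_effect = 0.25,
                          thickness_sd = 0.25,
                          female_effect_scale = 1,
                          iq_shift = 9,
                          iq_missing_rate = 0.1,
                          left_handed_rate = 0.1,
                          test_fraction = 1 / 3,
                          seed = 1) {
  if (length(n_subjects_per_gender) == 1) {
    n_subjects_per_gender <- rep(n_subjects_per_gender, 2)
  }
  names(n_subjects_per_gender) <- c("male", "female")
  names(adhd_prevalence_by_gender) <- c("male", "female")
  cfg <- list(
    n_subjects_per_gender = n_subjects_per_gender,
    adhd_prevalence_by_gender = adhd_prevalence_by_gender,
    n_sites = n_sites, site_effect_sd = site_effect_sd,
    n_regions = n_regions, n_timepoints = n_timepoints, tr = tr,
    band = band, n_effect_edges = n_effect_edges,
    effect_magnitude = effect_magnitude,
    icosphere_level = icosphere_level,
    n_effect_vertices = n_effect_vertices,
    thickness_effect = thickness_effect, thickness_sd = thickness_sd,
    female_effect_scale = female_effect_scale,
    iq_shift = iq_shift, iq_missing_rate = iq_missing_rate,
    left_handed_rate = left_handed_rate,
    test_fraction = test_fraction, seed = as.integer(seed))
  probs <- c(cfg$adhd_prevalence_by_gender, cfg$iq_missing_rate,
             cfg$left_handed_rate, cfg$test_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(cfg$n_subjects_per_gender, cfg$n_sites, cfg$n_regions,
              cfg$n_timepoints)
  if (any(counts <= 0)) stop("counts must be positive")
  nyq <- 1 / (2 * cfg$tr)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop(sprintf("band must lie inside (0, %g) Hz for tr = %g", nyq, cfg$tr))
  }
  max_edges <- cfg$n_regions * (cfg$n_regions - 1) / 2
  if (cfg$n_effect_edges > max_edges) {
    stop("n_effect_edges exceeds the number of region pairs")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# evaluate expr with a derived RNG substream, restoring the caller's state
with_substream <- function(seed, offset, expr) {
  sub <- (as.double(seed) * 1000003 + offset) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  expr
}

#' Group-specific sparse precision matrices
#'
#' Builds a shared sparse, symmetric, diagonally dominant (hence positive
#' definite) baseline precision, then perturbs `n_effect_edges` randomly
#' chosen off-diagonal pairs by `effect_magnitude` in the ADHD group only.
#' If the perturbation threatens positive definiteness the magnitude is
#' halved with a warning until both matrices are PD.
#'
#' @param config `cohort_config`.
#' @return list of class `ground_truth` with `precision_tdc`,
#'   `precision_adhd`, `effect_edges` (two-column index matrix), and the
#'   `effect_magnitude` actually applied.
#' @export
simulate_group_precisions <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  r <- config$n_regions
  with_substream(config$seed, 1, {
    # sparse baseline: a ring of partial correlations plus random chords,
    # strong enough that the implied marginal correlations (~0.4 on
    # connected pairs) match resting-state connectivity strengths
    theta <- diag(r)
    ring <- cbind(seq_len(r), c(seq_len(r)[-1], 1))
    if (r >= 3) theta[ring] <- theta[cbind(ring[, 2], ring[, 1])] <- -0.35
    n_chords <- max(0, round(r / 4))
    all_pairs <- which(upper.tri(diag(r)), arr.ind = TRUE)
    is_ring <- (all_pairs[, 2] - all_pairs[, 1] == 1) |
      (all_pairs[, 1] == 1 & all_pairs[, 2] == r)
    free <- which(!is_ring)
    if (n_chords > 0 && length(free) > 0) {
      chords <- all_pairs[free[sample.int(length(free),
                                          min(n_chords, length(free)))], ,
                          drop = FALSE]
      theta[chords] <- theta[cbind(chords[, 2], chords[, 1])] <- -0.25
    }
    # effect edges: prefer node-disjoint, currently-zero pairs so the
    # perturbation's spectral norm equals the effect magnitude
    k <- config$n_effect_edges
    cand <- seq_len(nrow(all_pairs))[theta[all_pairs] == 0]
    cand <- cand[sample.int(length(cand))]
    pick <- integer(0)
    used_nodes <- integer(0)
    for (ci in cand) {
      if (length(pick) == k) break
      pair <- all_pairs[ci, ]
      if (any(pair %in% used_nodes)) next
      pick <- c(pick, ci)
      used_nodes <- c(used_nodes, pair)
    }
    if (length(pick) < k) {   # fall back to shared-node / nonzero pairs
      rest <- setdiff(seq_len(nrow(all_pairs)), pick)
      pick <- c(pick, rest[sample.int(length(rest), k - length(pick))])
    }
    effect_edges <- if (k > 0) {
      all_pairs[pick, , drop = FALSE]
    } else matrix(integer(0), 0, 2)

    # inflate the diagonal to a *relative* margin: min eigenvalue at least
    # (0.05 + effect) times the diagonal, so that injecting effect edges at
    # partial-correlation scale provably keeps both matrices PD while the
    # baseline partial correlations stay near their nominal values
    mag <- min(config$effect_magnitude, 0.8)
    frac <- min(0.05 + mag, 0.9)
    ev0 <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev0 < frac) {
      delta <- (frac + 0.01 - ev0) / (1 - frac)
      theta <- theta + diag(delta, r)
    }
    theta_adhd <- theta
    if (nrow(effect_edges) > 0 && mag > 0) {
      # effect entries scaled by the diagonal: planted partial correlation
      # equals the configured magnitude exactly
      inj <- -mag * sqrt(diag(theta)[effect_edges[, 1]] *
                           diag(theta)[effect_edges[, 2]])
      theta_adhd[effect_edges] <- theta_adhd[effect_edges] + inj
      theta_adhd[cbind(effect_edges[, 2], effect_edges[, 1])] <-
        theta_adhd[effect_edges]
    }
    ev <- min(eigen(theta_adhd, symmetric = TRUE, only.values = TRUE)$values)
    repeat {
      if (ev > 1e-8 || mag == 0) break
      mag <- mag / 2
      warning(sprintf("effect magnitude infeasible; reduced to %g", mag))
      theta_adhd <- theta
      inj <- -mag * sqrt(diag(theta)[effect_edges[, 1]] *
                           diag(theta)[effect_edges[, 2]])
      theta_adhd[effect_edges] <- theta_adhd[effect_edges] + inj
      theta_adhd[cbind(effect_edges[, 2], effect_edges[, 1])] <-
        theta_adhd[effect_edges]
      ev <- min(eigen(theta_adhd, symmetric = TRUE, only.values = TRUE)$values)
    }
    structure(list(precision_tdc = theta, precision_adhd = theta_adhd,
                   effect_edges = effect_edges, effect_magnitude = mag),
              class = "ground_truth")
  })
}

#' Band-limited correlated Gaussian ROI signals
#'
#' Draws i.i.d. multivariate Gaussian timepoints with covariance equal to
#' the inverse of `precision`, then applies the zero-phase band-pass of
#' [bandpass_filter()] (which introduces the temporal autocorrelation that
#' the effective-sample-size correction downstream must handle). The
#' partial-correlation structure survives the common per-column filter.
#'
#' @param precision symmetric positive-definite precision matrix.
#' @param n_timepoints series length.
#' @param tr repetition time in seconds.
#' @param band band-pass edges (Hz).
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#' @param subject_id,session_id identifiers for the returned object.
#' @return `roi_timeseries`.
#' @export
simulate_timeseries <- function(precision, n_timepoints, tr = 2,
                                band = c(0.009, 0.08), seed = 1,
                                subject_id = "sim", session_id = "1") {
  ev <- eigen(precision, symmetric = TRUE)
  if (min(ev$values) <= 0) stop("precision matrix must be positive definite")
  nyq <- 1 / (2 * tr)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop(sprintf("band must lie inside (0, %g) Hz for tr = %g", nyq, tr))
  }
  r <- nrow(precision)
  # covariance = inverse precision; sample via its symmetric square root
  cov_half <- ev$vectors %*% (t(ev$vectors) / sqrt(ev$values))
  raw <- with_substream(seed, 2, {
    matrix(stats::rnorm(n_timepoints * r), n_timepoints, r) %*% t(cov_half)
  })
  ts <- roi_timeseries(raw, roi_labels(r), tr = tr,
                       subject_id = subject_id, session_id = session_id)
  bandpass_filter(ts, band[1], band[2])
}

#' Synthetic phenotype table
#'
#' Ages uniform on 7-21 years; handedness coded right/left/ambidextrous;
#' Verbal and Performance IQ Gaussian (SD 15) shifted down by `iq_shift`
#' for ADHD subjects; diagnosis drawn with gender-specific prevalence and
#' split into Combined / Inattentive / Hyperactive subtypes; sites assigned
#' round-robin; both IQ scores set missing together at `iq_missing_rate`.
#'
#' @param config `cohort_config`.
#' @param seed optional override of `config$seed`.
#' @return data frame with ADHD-200-style columns
#'   (`ID`, `Site`, `Gender`, `Age`, `Handedness`, `VerbalIQ`,
#'   `PerformanceIQ`, `DX`, plus the binary label and partition columns).
#' @export
simulate_phenotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n_m <- config$n_subjects_per_gender[["male"]]
  n_f <- config$n_subjects_per_gender[["female"]]
  n <- n_m + n_f
  with_substream(seed, 3, {
    gender <- c(rep("male", n_m), rep("female", n_f))
    prev <- config$adhd_prevalence_by_gender[gender]
    is_adhd <- stats::rbinom(n, 1, prev) == 1
    subtype <- ifelse(is_adhd,
                      sample(c("ADHD-Combined", "ADHD-Inattentive",
                               "ADHD-Hyperactive"),
                             n, replace = TRUE, prob = c(0.5, 0.45, 0.05)),
                      "TDC")
    age <- stats::runif(n, 7, 21)
    hand <- sample(c("right", "left", "ambidextrous"), n, replace = TRUE,
                   prob = c(1 - config$left_handed_rate - 0.02,
                            config$left_handed_rate, 0.02))
    viq <- stats::rnorm(n, 110, 15) - config$iq_shift * is_adhd
    piq <- stats::rnorm(n, 108, 15) - config$iq_shift * is_adhd
    missing <- stats::rbinom(n, 1, config$iq_missing_rate) == 1
    viq[missing] <- NA_real_
    piq[missing] <- NA_real_
    site <- rep(seq_len(config$n_sites), length.out = n)
    ph <- data.frame(
      ID = sprintf("sub%04d", seq_len(n)),
      Site = paste0("site", site),
      Gender = gender,
      Age = age,
      Handedness = hand,
      VerbalIQ = viq,
      PerformanceIQ = piq,
      DX = subtype,
      stringsAsFactors = FALSE)
    ph$label <- ifelse(is_adhd, 1L, -1L)
    # deterministic stratified test split: sort, deal every k-th to test
    if (config$test_fraction > 0) {
      ord <- order(ph$Gender, ph$label, ph$Site, ph$Age, ph$ID)
      k <- max(2L, round(1 / config$test_fraction))
      test_ids <- ph$ID[ord][seq_along(ord) %% k == 0]
      ph$partition <- ifelse(ph$ID %in% test_ids, "test", "train")
    } else {
      ph$partition <- "train"
    }
    ph
  })
}

#' Synthetic anatomical tables
#'
#' Per-subject vertex thickness (Gaussian around a smooth cohort mean
#' surface of about 2.5 mm) with the group shift `thickness_effect`
#' subtracted at the effect vertices for ADHD subjects (scaled by
#' `female_effect_scale` in girls); per-ROI morphometric statistics; and
#' subcortical structure volumes plus an intracranial volume. Additive
#' per-site offsets shift the anatomical means.
#'
#' @param config `cohort_config`.
#' @param phenotypes table from [simulate_phenotypes()].
#' @param seed optional override of `config$seed`.
#' @return list with `records` (one `anatomical_record` per subject, named
#'   by ID), the `effect_vertices` index vector, and the `manifest`.
#' @export
simulate_anatomy <- function(config, phenotypes, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  nv <- icosphere_vertex_count(config$icosphere_level)
  manifest <- anatomy_manifest()
  n <- nrow(phenotypes)
  with_substream(seed, 4, {
    base_lh <- 2.5 + 0.3 * sin(seq_len(nv) / 7)
    base_rh <- 2.5 + 0.3 * cos(seq_len(nv) / 7)
    effect_vertices <- sample(nv, min(config$n_effect_vertices, nv))
    site_shift <- stats::rnorm(config$n_sites, 0, config$site_effect_sd)
    names(site_shift) <- paste0("site", seq_len(config$n_sites))
    records <- vector("list", n)
    names(records) <- phenotypes$ID
    rois <- manifest$cortical_rois
    for (i in seq_len(n)) {
      is_adhd <- phenotypes$label[i] == 1
      eff <- config$thickness_effect *
        (if (phenotypes$Gender[i] == "female") config$female_effect_scale else 1)
      shift <- site_shift[[phenotypes$Site[i]]]
      lh <- stats::rnorm(nv, base_lh + shift, config$thickness_sd)
      rh <- stats::rnorm(nv, base_rh + shift, config$thickness_sd)
      if (is_adhd && length(effect_vertices) > 0) {
        lh[effect_vertices] <- lh[effect_vertices] - eff
      }
      lh <- pmax(lh, 0)
      rh <- pmax(rh, 0)
      rs <- data.frame(
        thickness_avg = stats::rnorm(length(rois), 2.5 + shift, 0.15),
        thickness_sd = abs(stats::rnorm(length(rois), 0.4, 0.05)),
        area_avg = stats::rnorm(length(rois), 1200, 150),
        area_sd = abs(stats::rnorm(length(rois), 120, 20)),
        volume_avg = stats::rnorm(length(rois), 3200, 400),
        volume_sd = abs(stats::rnorm(length(rois), 300, 50)),
        curv_avg = stats::rnorm(length(rois), 0.12, 0.02),
        curv_sd = abs(stats::rnorm(length(rois), 0.03, 0.005)),
        row.names = rois)
      icv <- stats::rnorm(1, 1.5e6, 1.2e5)
      vols <- stats::setNames(
        abs(stats::rnorm(length(manifest$structures), 6000, 900)),
        manifest$structures)
      vols[c("wm_hypointensities", "gm_hypointensities")] <-
        abs(stats::rnorm(2, 1500, 400))
      records[[i]] <- anatomical_record(lh, rh, rs, vols, icv)
    }
    list(records = records, effect_vertices = sort(effect_vertices),
         manifest = manifest)
  })
}

#' Generate a complete synthetic cohort
#'
#' Joins phenotypes, group-specific precision matrices, per-subject
#' band-limited time series, and anatomical records into one bundle with
#' its ground truth. The planted network effect is scaled by
#' `female_effect_scale` for girls by interpolating the two group
#' precisions. With `out_dir` set, all standard files are written
#' (per-subject time-series TSV, phenotype CSV, anatomy TSV, ground-truth
#' JSON).
#'
#' @param config `cohort_config`.
#' @param out_dir optional output directory.
#' @return list of class `synthetic_cohort` with `config`, `phenotypes`,
#'   `timeseries` (named list of `roi_timeseries`), `anatomy`, `truth`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  truth <- simulate_group_precisions(config)
  phenotypes <- simulate_phenotypes(config)
  anatomy <- simulate_anatomy(config, phenotypes)
  n <- nrow(phenotypes)
  site_gain <- with_substream(config$seed, 5, {
    stats::setNames(exp(stats::rnorm(config$n_sites, 0, config$site_effect_sd)),
                    paste0("site", seq_len(config$n_sites)))
  })
  timeseries <- vector("list", n)
  names(timeseries) <- phenotypes$ID
  for (i in seq_len(n)) {
    is_adhd <- phenotypes$label[i] == 1
    scale_f <- if (phenotypes$Gender[i] == "female") config$female_effect_scale else 1
    prec <- if (is_adhd) {
      truth$precision_tdc +
        scale_f * (truth$precision_adhd - truth$precision_tdc)
    } else {
      truth$precision_tdc
    }
    ts <- simulate_timeseries(prec, config$n_timepoints, config$tr,
                              config$band,
                              seed = config$seed * 131 + i,
                              subject_id = phenotypes$ID[i])
    ts$values <- ts$values * site_gain[[phenotypes$Site[i]]]
    timeseries[[i]] <- ts
  }
  truth$group_labels <- stats::setNames(phenotypes$label, phenotypes$ID)
  truth$effect_vertices <- anatomy$effect_vertices
  cohort <- structure(
    list(config = config, phenotypes = phenotypes, timeseries = timeseries,
         anatomy = anatomy, truth = truth),
    class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}
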