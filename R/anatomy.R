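#' Subdivided-icosahedron sphere mesh
#'
#' Recursively subdivides a regular icosahedron: each triangle splits into
#' four, edge midpoints (shared between neighbouring faces and deduplicated)
#' are projected onto the unit sphere. Level `k` has `10 * 4^k + 2` vertices
#' and `20 * 4^k` faces; level 4 gives the 2,562 vertices per hemisphere
#' used for the thickness resampling grid.
#'
#' @param level subdivision level, a nonnegative integer.
#' @return list with `vertices` (V x 3 unit-norm coordinates), `faces`
#'   (F x 3 vertex indices), `subdivision_level`.
#' @export
make_icosphere <- function(level = 4) {
  stopifnot(level >= 0, level == round(level))
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b), sep = "-")
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    new_f <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      new_f[(t - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- new_f
  }
  list(vertices = v, faces = f, subdivision_level = as.integer(level))
}

icosphere_vertex_count <- function(level) 10L * 4L^level + 2L

#' Default anatomical label manifest
#'
#' Names for the cortical parcellation ROIs and subcortical structures used
#' by the anatomical feature schema. The defaults mirror a standard gyral
#' parcellation (configurable count per hemisphere) plus a conventional
#' subcortical segmentation including gray-/white-matter hypointensity
#' volumes; real tallies are data-dependent, so counts are parameters, not
#' constants.
#'
#' @param n_cortical_roi cortical ROIs per hemisphere.
#' @return list with `cortical_rois` (both hemispheres) and `structures`.
#' @export
anatomy_manifest <- function(n_cortical_roi = 34) {
  rois <- as.vector(outer(c("lh", "rh"),
                          sprintf("ctx%02d", seq_len(n_cortical_roi)),
                          paste, sep = "_"))
  structures <- c(
    "left_thalamus", "right_thalamus", "left_caudate", "right_caudate",
    "left_putamen", "right_putamen", "left_pallidum", "right_pallidum",
    "left_hippocampus", "right_hippocampus", "left_amygdala",
    "right_amygdala", "left_accumbens", "right_accumbens",
    "brainstem", "corpus_callosum",
    "wm_hypointensities", "gm_hypointensities")
  list(cortical_rois = sort(rois), structures = structures)
}

roi_stat_names <- c("thickness_avg", "thickness_sd", "area_avg", "area_sd",
                    "volume_avg", "volume_sd", "curv_avg", "curv_sd")

#' One subject's anatomical record
#'
#' @param thickness_lh,thickness_rh per-vertex cortical thickness (mm), one
#'   value per icosphere vertex, equal counts in the two hemispheres.
#' @param roi_stats data frame with one row per cortical ROI (rownames are
#'   ROI names) and the columns of `roi_stat_names`.
#' @param structure_volumes named vector of structure volumes in mm^3.
#' @param icv total intracranial volume in mm^3 (positive).
#' @return object of class `anatomical_record`.
#' @export
anatomical_record <- function(thickness_lh, thickness_rh, roi_stats,
                              structure_volumes, icv) {
  if (length(thickness_lh) != length(thickness_rh)) {
    stop("hemispheres must carry equal vertex counts")
  }
  if (any(c(thickness_lh, thickness_rh) < 0)) stop("thickness must be >= 0")
  if (!is.numeric(icv) || icv <= 0) stop("icv must be positive")
  structure(
    list(thickness_lh = as.numeric(thickness_lh),
         thickness_rh = as.numeric(thickness_rh),
         roi_stats = roi_stats,
         structure_volumes = structure_volumes,
         icv = icv),
    class = "anatomical_record"
  )
}

#' ICV-normalised volume features
#'
#' Divides every structure volume (including the hypointensity volumes) by
#' the subject's total intracranial volume, controlling for head-size and
#' age effects. Thickness and curvature statistics are left unscaled.
#'
#' @param record `anatomical_record`.
#' @return named vector `volnorm_<structure>`.
#' @export
normalize_volumes <- function(record) {
  stopifnot(inherits(record, "anatomical_record"))
  if (record$icv <= 0) stop("icv must be positive")
  out <- record$structure_volumes / record$icv
  names(out) <- paste0("volnorm_", names(record$structure_volumes))
  out
}

#' Assemble one subject's anatomical feature vector
#'
#' Concatenates per-vertex thickness for both hemispheres (names
#' `thick_<lh|rh>_v<index>`), the per-ROI morphometric statistics, and the
#' ICV-normalised structure volumes. Average-curvature vertex maps are not
#' part of the schema. Constant features are excluded cohort-wide during
#' table assembly, never per subject.
#'
#' @param record `anatomical_record`.
#' @return named numeric feature vector.
#' @export
assemble_anatomical_features <- function(record) {
  stopifnot(inherits(record, "anatomical_record"))
  nv <- length(record$thickness_lh)
  vfmt <- paste0("v%0", max(4, nchar(nv)), "d")
  thick <- c(
    stats::setNames(record$thickness_lh,
                    paste0("thick_lh_", sprintf(vfmt, seq_len(nv)))),
    stats::setNames(record$thickness_rh,
                    paste0("thick_rh_", sprintf(vfmt, seq_len(nv)))))
  rs <- record$roi_stats
  roi <- unlist(lapply(rownames(rs), function(r) {
    stats::setNames(as.numeric(rs[r, roi_stat_names]),
                    paste0("roi_", r, "_", roi_stat_names))
  }))
  c(thick, roi, normalize_volumes(record))
}

#' Decompose a thickness feature name
#'
#' @param name a `thick_<hemi>_v<index>` feature name.
#' @return list with `hemisphere` and integer `vertex`.
#' @export
parse_thickness_feature <- function(name) {
  m <- regmatches(name, regexec("^thick_(lh|rh)_v0*([0-9]+)$", name))[[1]]
  if (length(m) != 3) stop("not a thickness feature name")
  list(hemisphere = m[2], vertex = as.integer(m[3]))
}
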