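#' Mean map value within a spherical ROI
#'
#' Averages a 3D statistical map over the voxels whose centers lie within
#' the sphere's radius (inclusive) of its center.  Coordinates are
#' continuous mm in the volume's own frame: voxel `[i, j, l]`'s center is
#' `origin + (c(i, j, l) - 1) * voxel_size`.
#'
#' @param map 3D numeric array.
#' @param roi a [roi_spec()].
#' @param voxel_size voxel edge lengths in mm (length 1 or 3; study maps
#'   were resampled to 3 mm).
#' @param origin mm coordinate of voxel `[1,1,1]`'s center.
#' @return mean value over the sphere's voxels; `NA` with a warning when
#'   the sphere covers no voxel center.
#' @export
sphere_roi_values <- function(map, roi, voxel_size = c(3, 3, 3),
                              origin = c(0, 0, 0)) {
  idx <- sphere_roi_indices(dim(map), roi, voxel_size, origin)
  if (!length(idx)) {
    warning("sphere ROI ", roi$name %||% "", " covers no voxel center")
    return(NA_real_)
  }
  mean(map[idx])
}

#' @rdname sphere_roi_values
#' @param dim 3D grid dimensions.
#' @return `sphere_roi_indices`: integer vector of linear voxel indices.
#' @export
sphere_roi_indices <- function(dim, roi, voxel_size = c(3, 3, 3),
                               origin = c(0, 0, 0)) {
  stopifnot(inherits(roi, "roi_spec"), length(dim) == 3L)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 1) * voxel_size[a])
  # squared distance decomposes over axes
  d1 <- (ax[[1]] - roi$center[1])^2
  d2 <- (ax[[2]] - roi$center[2])^2
  d3 <- (ax[[3]] - roi$center[3])^2
  g <- outer(outer(d1, d2, "+"), d3, "+")
  which(g <= roi$radius^2 + 1e-9)
}

#' Second-level (random-effects) ROI statistics
#'
#' One-sample t tests of per-subject contrast values against zero, ROI by
#' ROI, with Bonferroni correction over the ROI family (per-ROI threshold
#' `alpha / n_rois`; 25 ROIs at alpha 0.05 give 0.002).
#'
#' @param values numeric matrix, subjects x ROIs (a vector is one ROI).
#' @param alpha family-wise alpha (default 0.05).
#' @return list with `table` (data.frame: `roi`, `mean`, `sem`, `t`,
#'   `dof`, `p`, `significant`), `p_threshold`, and `correction`.
#' @export
second_level <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  n_roi <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("roi", seq_len(n_roi))
  thr <- alpha / n_roi
  rows <- lapply(seq_len(n_roi), function(j) {
    x <- values[, j]
    gs <- group_tests(x, "one_sample")
    data.frame(roi = colnames(values)[j], mean = mean(x, na.rm = TRUE),
               sem = stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
               t = gs$statistic, dof = gs$df1, p = gs$p,
               significant = !is.na(gs$p) & gs$p < thr,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), p_threshold = thr,
       correction = "Bonferroni")
}

#' Second-level phase-course test
#'
#' One-way within-subject ANOVA (Greenhouse-Geisser corrected) over the
#' matched-contrast values of the five period roles, assessing how
#' error-specific activity evolves before, during and after errors.
#'
#' @param values numeric matrix, subjects x roles (PreE2..PostE2).
#' @return a `GroupStat` row from [group_tests()].
#' @export
second_level_phase <- function(values) {
  group_tests(values, "rm_anova")
}
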