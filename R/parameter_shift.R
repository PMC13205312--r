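# Shift of HSI tissue parameters between the pre-, intra- and post-ICG
# acquisitions. A combined HSI + ICG-FA workflow requires that circulating
# ICG leaves the tissue indices essentially unchanged; this module
# summarises per-ROI differences descriptively (no hypothesis testing: the
# acquisition protocol cannot separate ICG presence from temporal drift).

#' Mean parameter value over a circular ROI
#'
#' @param map a `parameter_map` (see [compute_index_map()]) or a plain
#'   numeric matrix.
#' @param roi a [circular_roi()] fully inside the map.
#' @return scalar mean over the ROI disc.
#' @export
roi_parameter_value <- function(map, roi) {
  m <- if (inherits(map, "parameter_map")) map$values else map
  roi_check_inside(roi, nrow(m), ncol(m), "map")
  idx <- disc_indices(roi$x, roi$y, roi$r, nrow(m), ncol(m))
  mean(m[idx])
}

#' Summarise tissue-parameter shifts across acquisitions
#'
#' For every parameter and ROI, computes the differences of ROI means
#' `intra - pre` and `post - pre`, then groups the differences by
#' perfusion class and reports the median, interquartile range and ROI
#' count per (parameter, comparison, class) cell, in parameter points on
#' the 0-100 scale. Classes without ROIs are omitted with a warning.
#'
#' @param maps_pre,maps_intra,maps_post named lists of `parameter_map`s
#'   (same parameter names across acquisitions); `maps_intra` or
#'   `maps_post` may be `NULL`, dropping that comparison.
#' @param rois list of [circular_roi()]s with perfusion classes; geometry
#'   must be identical across acquisitions (co-registered images).
#' @return data frame with columns `parameter`, `comparison`, `class`,
#'   `median_diff`, `iqr`, `n_rois`.
#' @export
shift_summary <- function(maps_pre, maps_intra = NULL, maps_post = NULL, rois) {
  if (length(rois) == 0L) validation_error("at least one ROI is required")
  if (is.null(maps_intra) && is.null(maps_post))
    validation_error("at least one of maps_intra, maps_post is required")
  params <- sort(names(maps_pre))
  classes <- c("perfused", "transition", "ischemic")
  roi_class <- vapply(rois, `[[`, "", "perfusion_class")
  seen <- unique(roi_class)
  for (cl in setdiff(classes, seen))
    warning(sprintf("no ROIs in class '%s'; cells omitted", cl))
  comparisons <- list()
  if (!is.null(maps_intra)) comparisons[["intra-pre"]] <- maps_intra
  if (!is.null(maps_post)) comparisons[["post-pre"]] <- maps_post
  rows <- list()
  for (p in params) {
    pre_vals <- vapply(rois, function(r) roi_parameter_value(maps_pre[[p]], r), 0)
    for (cmp in names(comparisons)) {
      other <- comparisons[[cmp]][[p]]
      if (is.null(other))
        config_error(sprintf("parameter '%s' missing from %s maps", p, cmp))
      diffs <- vapply(rois, function(r) roi_parameter_value(other, r), 0) - pre_vals
      for (cl in intersect(classes, seen)) {
        d <- diffs[roi_class == cl]
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, comparison = cmp, class = cl,
          median_diff = stats::median(d),
          iqr = stats::IQR(d),
          n_rois = length(d), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
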