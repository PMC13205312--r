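# Annotation interchange. The JSON schema is shared with the Python-based
# intraoperative annotation tool and is 0-based:
# {rois:[{x,y,r,label,class}], ruler:{p0:[x,y], p1:[x,y], cm:number},
#  clinical_marker:[x,y], profile_lines:[{p0:[x,y], p1:[x,y]}]}.
# Coordinates are shifted to R's 1-based convention on read.

#' Annotation set
#'
#' @param rois list of [circular_roi()]s.
#' @param ruler list `(p0, p1, cm)`: ruler calibration points (1-based
#'   pixel coords) and their true distance in cm; may be `NULL`.
#' @param clinical_marker clinical transection marker `c(x, y)`; may be
#'   `NULL`.
#' @param profile_lines list of `list(p0, p1)` border line profiles.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(rois = list(), ruler = NULL, clinical_marker = NULL,
                           profile_lines = list()) {
  for (r in rois) if (!inherits(r, "circular_roi"))
    validation_error("rois must be circular_roi objects")
  structure(list(rois = rois, ruler = ruler, clinical_marker = clinical_marker,
                 profile_lines = profile_lines),
            class = "annotation_set")
}

#' Read annotations from interchange JSON
#'
#' @param path JSON file path (0-based coordinates).
#' @return an [annotation_set()] with 1-based coordinates.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) format_error(sprintf("annotation file '%s' not found", path))
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rois <- lapply(j$rois, function(e)
    circular_roi(e$x + 1, e$y + 1, e$r,
                 label = if (is.null(e$label)) "" else e$label,
                 perfusion_class = if (is.null(e$class)) "perfused" else e$class))
  ruler <- if (!is.null(j$ruler))
    list(p0 = unlist(j$ruler$p0) + 1, p1 = unlist(j$ruler$p1) + 1, cm = j$ruler$cm)
  marker <- if (!is.null(j$clinical_marker)) unlist(j$clinical_marker) + 1
  lines <- lapply(j$profile_lines, function(e)
    list(p0 = unlist(e$p0) + 1, p1 = unlist(e$p1) + 1))
  annotation_set(rois, ruler, marker, lines)
}

#' Write annotations to interchange JSON
#'
#' @param ann an [annotation_set()] (1-based coordinates).
#' @param path output JSON path (written 0-based).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  j <- list(
    rois = lapply(ann$rois, function(r)
      list(x = r$x - 1, y = r$y - 1, r = r$r, label = r$label,
           class = r$perfusion_class)),
    profile_lines = lapply(ann$profile_lines, function(e)
      list(p0 = as.numeric(e$p0) - 1, p1 = as.numeric(e$p1) - 1))
  )
  if (!is.null(ann$ruler))
    j$ruler <- list(p0 = as.numeric(ann$ruler$p0) - 1,
                    p1 = as.numeric(ann$ruler$p1) - 1, cm = ann$ruler$cm)
  if (!is.null(ann$clinical_marker))
    j$clinical_marker <- as.numeric(ann$clinical_marker) - 1
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
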