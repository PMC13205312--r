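# End-to-end study replica for one surgical case and for a cohort.
# Timeline per case: pre-cube before ICG administration (tissue indices),
# ICG video from the bolus through the inflow phase (inflow metrics),
# intra-cube near maximum fluorescence and post-cube after washout
# (reconstruction, parameter shift), border localisation across the
# co-registered modality images, and cohort statistics on the collected
# signed border distances.

#' Pipeline configuration with the study defaults
#'
#' All tunables in one place: spectral smoothing sigma 4.44 band units,
#' reconstruction window 790-810 nm, 7 x 7 median kernel, 99th-percentile
#' normalisation, 3-s moving average, 3-6 s background-noise window,
#' slope-run fraction 0.5, literature thresholds (2.1 units/s, 60 s,
#' 40 s), clinically relevant difference 0.5 cm, alpha 0.05.
#'
#' @param ... overrides for individual entries.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sigma_bands = 4.44,
    band_window_nm = c(790, 810),
    median_kernel = 7L,
    percentile = 99,
    movmean_window_s = 3,
    noise_window_s = c(3, 6),
    slope_fraction = 0.5,
    thresholds = list(wada_slope = 2.1, hayami_t0 = 60, kim_t0 = 40),
    delta_cm = 0.5,
    alpha = 0.05,
    profile_step_px = 0.5,
    profile_smooth_window = 5L,
    indices = default_index_definitions(),
    reference_modality = "ICG"
  )
  override <- list(...)
  for (k in names(override)) {
    if (!k %in% names(cfg)) config_error(sprintf("unknown config entry '%s'", k))
    cfg[[k]] <- override[[k]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Case bundle
#'
#' Paths (or in-memory objects) for one case. The pre-cube and the
#' annotations are mandatory; an intra- or post-cube is required for
#' reconstruction; the frame stack is optional (the inflow stage is
#' skipped without it).
#'
#' @param case_id case identifier.
#' @param pre_cube path to the pre-ICG ENVI cube (or an [hs_cube()]).
#' @param intra_cube,post_cube optional cubes after ICG administration.
#' @param frames optional frame-stack path (or a [frame_stack()]).
#' @param annotations annotation JSON path (or an [annotation_set()]).
#' @param indicator optional indicator region `list(x, y, w, h)` for laser
#'   normalisation; `NULL` assumes constant full laser power.
#' @param bank optional [laser_template_bank()].
#' @return object of class `case_bundle`.
#' @export
case_bundle <- function(case_id, pre_cube, intra_cube = NULL, post_cube = NULL,
                        frames = NULL, annotations, indicator = NULL,
                        bank = laser_template_bank()) {
  if (is.null(pre_cube)) validation_error("pre_cube is mandatory")
  if (is.null(annotations)) validation_error("annotations are mandatory")
  structure(list(case_id = case_id, pre_cube = pre_cube,
                 intra_cube = intra_cube, post_cube = post_cube,
                 frames = frames, annotations = annotations,
                 indicator = indicator, bank = bank),
            class = "case_bundle")
}

resolve_cube <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "hs_cube")) x else read_cube(x)
}

resolve_stack <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "frame_stack")) x else read_frame_stack(x)
}

resolve_annotations <- function(x) {
  if (inherits(x, "annotation_set")) x else read_annotations(x)
}

#' Write a parameter or reconstruction map as 32-bit float TIFF
#'
#' @param map `parameter_map`, `rec_icg_image` or numeric matrix.
#' @param path output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  m <- if (is.list(map)) map$values else map
  tiff::writeTIFF(m / max(1, max(m)), path, bits.per.sample = 32L)
  invisible(path)
}

log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the full pipeline for one case
#'
#' Executes, in order: tissue indices on the pre-cube, ICG reconstruction
#' on the intra- (preferred) or post-cube, inflow metrics per ROI from the
#' frame stack, border distances across the available modality images
#' (StO2 from the pre-cube, reconstructed ICG, and the ICG fluorescence
#' image formed as the pixel-wise maximum of the laser-normalised frames),
#' and the pre/intra/post parameter-shift summary. Stages whose inputs are
#' missing are recorded as skipped; the run is deterministic given inputs
#' and configuration.
#'
#' @param bundle a [case_bundle()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, metrics, maps and
#'   the log are written there (`metrics.csv`, `border.csv`, `shift.csv`,
#'   `maps/`, `case.log`).
#' @return list of class `case_report`: `case_id`, `indices`, `rec_icg`,
#'   `inflow` (data frame per ROI), `border` (data frame per modality),
#'   `shift`, `skipped`, `log`.
#' @export
run_case <- function(bundle, config = pipeline_config(), out_dir = NULL) {
  if (!inherits(bundle, "case_bundle")) validation_error("bundle must be a case_bundle")
  ann <- resolve_annotations(bundle$annotations)
  pre <- resolve_cube(bundle$pre_cube)
  intra <- resolve_cube(bundle$intra_cube)
  post <- resolve_cube(bundle$post_cube)
  stack <- resolve_stack(bundle$frames)
  log <- character()
  skipped <- character()
  log <- log_line(log, "case %s: %d ROIs, %d profile lines", bundle$case_id,
                  length(ann$rois), length(ann$profile_lines))

  # tissue indices on the pre-cube
  indices <- compute_all_indices(pre, config$indices)
  log <- log_line(log, "indices: %s", paste(names(indices), collapse = ", "))

  # reconstruction on intra (preferred) or post cube
  rec_src <- if (!is.null(intra)) intra else post
  rec <- NULL
  if (is.null(rec_src)) {
    skipped <- c(skipped, "reconstruction")
    log <- log_line(log, "reconstruction skipped: no intra/post cube")
  } else {
    rec <- reconstruct_icg(rec_src, config$sigma_bands, config$band_window_nm,
                           config$median_kernel, config$percentile)
    log <- log_line(log, "reconstruction from %s-cube (sigma=%.2f, window=%.0f-%.0f nm)",
                    rec$source_tag, config$sigma_bands,
                    config$band_window_nm[1], config$band_window_nm[2])
  }

  # inflow metrics per ROI
  inflow_df <- NULL
  if (is.null(stack)) {
    skipped <- c(skipped, "inflow")
    log <- log_line(log, "inflow skipped: no frame stack")
  } else {
    rows <- lapply(ann$rois, function(roi) {
      m <- tryCatch({
        curve <- build_curve(stack, roi, bundle$indicator, bundle$bank,
                             config$movmean_window_s)
        inflow_metrics(curve, config$slope_fraction, config$thresholds)
      }, icgperf_error = function(e) e)
      if (inherits(m, "condition")) {
        log <<- log_line(log, "inflow ROI '%s' failed: %s", roi$label,
                         conditionMessage(m))
        return(data.frame(label = roi$label, class = roi$perfusion_class,
                          B = NA_real_, t0_s = NA_real_, slope = NA_real_,
                          ttp_s = NA_real_, wada_slope_lt_2.1 = NA,
                          hayami_t0_gt_60 = NA, kim_t0_gt_40 = NA,
                          stringsAsFactors = FALSE))
      }
      data.frame(label = roi$label, class = roi$perfusion_class,
                 B = m$background_noise_B, t0_s = m$t0_objective_s,
                 slope = m$slope_units_per_s, ttp_s = m$ttp_s,
                 wada_slope_lt_2.1 = m$threshold_flags$wada_slope_lt_2.1,
                 hayami_t0_gt_60 = m$threshold_flags$hayami_t0_gt_60,
                 kim_t0_gt_40 = m$threshold_flags$kim_t0_gt_40,
                 stringsAsFactors = FALSE)
    })
    inflow_df <- do.call(rbind, rows)
    log <- log_line(log, "inflow: %d ROI curves (%d usable)", nrow(inflow_df),
                    sum(!is.na(inflow_df$t0_s)))
  }

  # border distances across modalities
  border_df <- NULL
  if (length(ann$profile_lines) == 3L && !is.null(ann$clinical_marker) &&
      !is.null(ann$ruler)) {
    scale <- calibrate_scale(ann$ruler$p0, ann$ruler$p1, ann$ruler$cm)
    images <- list()
    if ("StO2" %in% names(indices)) images$StO2 <- indices$StO2$values
    if (!is.null(rec)) images$recICG <- rec$values
    if (!is.null(stack)) {
      laser <- if (is.null(bundle$indicator)) rep(1, dim(stack$frames)[3])
               else estimate_laser_series(stack, bundle$indicator, bundle$bank)
      d <- dim(stack$frames)
      norm <- sweep(matrix(stack$frames, d[1] * d[2], d[3]), 2L, laser, "/")
      images$ICG <- matrix(apply(norm, 1L, max), d[1], d[2])
    }
    rows <- list()
    for (mod in names(images)) {
      got <- tryCatch(
        suppressWarnings(border_distances(images[mod], ann$profile_lines,
                                          ann$clinical_marker, scale,
                                          config$profile_step_px,
                                          config$profile_smooth_window)),
        icgperf_error = function(e) e)
      if (inherits(got, "condition")) {
        log <- log_line(log, "border modality '%s' failed: %s", mod,
                        conditionMessage(got))
      } else {
        rows[[mod]] <- got
      }
    }
    if (length(rows) > 0) {
      border_df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      log <- log_line(log, "border: %d modalities, scale %.4f cm/px",
                      nrow(border_df), scale)
    } else {
      skipped <- c(skipped, "border")
      log <- log_line(log, "border skipped: no modality produced an estimate")
    }
  } else {
    skipped <- c(skipped, "border")
    log <- log_line(log, "border skipped: incomplete annotations (need 3 profiles, marker, ruler)")
  }

  # parameter shift pre vs intra/post
  shift_df <- NULL
  if ((!is.null(intra) || !is.null(post)) && length(ann$rois) > 0) {
    maps_intra <- if (!is.null(intra)) compute_all_indices(intra, config$indices)
    maps_post <- if (!is.null(post)) compute_all_indices(post, config$indices)
    shift_df <- withCallingHandlers(
      shift_summary(indices, maps_intra, maps_post, ann$rois),
      warning = function(w) invokeRestart("muffleWarning"))
    log <- log_line(log, "shift: %d cells", nrow(shift_df))
  } else {
    skipped <- c(skipped, "shift")
    log <- log_line(log, "shift skipped: no intra/post cube or no ROIs")
  }

  report <- structure(list(case_id = bundle$case_id, indices = indices,
                           rec_icg = rec, inflow = inflow_df,
                           border = border_df, shift = shift_df,
                           skipped = skipped, log = log),
                      class = "case_report")
  if (!is.null(out_dir)) write_case_report(report, out_dir)
  report
}

write_case_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$inflow))
    utils::write.csv(report$inflow, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(report$border))
    utils::write.csv(report$border, file.path(out_dir, "border.csv"), row.names = FALSE)
  if (!is.null(report$shift))
    utils::write.csv(report$shift, file.path(out_dir, "shift.csv"), row.names = FALSE)
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  for (nm in names(report$indices))
    write_map_tiff(report$indices[[nm]], file.path(maps_dir, paste0(nm, ".tiff")))
  if (!is.null(report$rec_icg))
    write_map_tiff(report$rec_icg, file.path(maps_dir, "recICG.tiff"))
  writeLines(report$log, file.path(out_dir, "case.log"))
  invisible(out_dir)
}

#' Run the cohort aggregation over case reports
#'
#' Collects the per-case signed border distances and produces the
#' modality comparison report (medians, paired Wilcoxon tests against the
#' reference modality, retrospective power). Cases without border results
#' are dropped with a logged count.
#'
#' @param reports list of `case_report`s from [run_case()], or a data
#'   frame of distances with columns `case`, `modality`, `distance_cm`.
#' @param config a [pipeline_config()].
#' @return see [modality_comparison_report()].
#' @export
run_cohort <- function(reports, config = pipeline_config()) {
  if (is.data.frame(reports)) {
    distances <- reports
  } else {
    if (length(reports) < 3L) validation_error("a cohort needs at least 3 cases")
    rows <- lapply(reports, function(r) {
      if (is.null(r$border)) return(NULL)
      data.frame(case = r$case_id, modality = r$border$modality,
                 distance_cm = r$border$signed_distance_cm,
                 stringsAsFactors = FALSE)
    })
    n_missing <- sum(vapply(rows, is.null, TRUE))
    if (n_missing > 0) message(sprintf("%d case(s) without border results dropped", n_missing))
    distances <- do.call(rbind, rows)
    if (is.null(distances) || length(unique(distances$case)) < 3L)
      validation_error("fewer than 3 cases with border results")
  }
  modality_comparison_report(distances, config$reference_modality,
                             config$delta_cm, config$alpha)
}
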