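#' Pipeline configuration
#'
#' Bundles every tunable of the image-analysis chain — feature scales,
#' probability threshold, minimum object area, connectivity and pixel pitch
#' — into one object whose hash is stamped into every output table for
#' provenance.
#'
#' @param features A [feature_config()].
#' @param threshold Probability threshold for [binarize()] (default 0.5).
#' @param min_area_px Minimum nucleus area in pixels (default 200).
#' @param connectivity 4 or 8 (default 8).
#' @param pixel_pitch Micrometres per pixel side (default 0.3225).
#' @return A `pipeline_config` object with a `hash` field.
#' @export
pipeline_config <- function(features = feature_config(), threshold = 0.5,
                            min_area_px = 200L, connectivity = 8L,
                            pixel_pitch = 0.3225) {
  stopifnot(inherits(features, "feature_config"))
  cfg <- list(features = features, threshold = threshold,
              min_area_px = as.integer(min_area_px),
              connectivity = as.integer(connectivity),
              pixel_pitch = pixel_pitch)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Segment and measure one field
#'
#' Runs the full per-field chain: feature stack, pixel classification,
#' binarization, connected-component labeling, size filtering, per-nucleus
#' measurement. Per-stage object counts are attached as the `stage_counts`
#' attribute (and checked: filtering never increases the count).
#'
#' @param dapi,gh2ax Numeric intensity matrices of the same shape.
#' @param model A `pixel_classifier`.
#' @param config A [pipeline_config()]; its feature configuration must match
#'   the one the model was trained with.
#' @return Tibble of nucleus records (see [measure_nuclei()]) with attribute
#'   `stage_counts` = (n_foreground_px, n_components, n_nuclei) and
#'   attribute `labels` holding the filtered label map.
#' @export
run_field <- function(dapi, gh2ax, model, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!identical(dim(dapi), dim(gh2ax))) {
    stop("`dapi` and `gh2ax` must share the same shape.", call. = FALSE)
  }
  if (!identical(model$config_hash, config$features$hash)) {
    stop("model was trained with a different feature configuration than `config`.",
         call. = FALSE)
  }
  stack <- compute_features(dapi, config$features)
  pmap <- predict_nucleus_prob(model, stack)
  mask <- binarize(pmap, config$threshold)
  labels <- label_components(mask, config$connectivity)
  filtered <- filter_small(labels, config$min_area_px)
  n_before <- attr(labels, "n_objects")
  n_after <- attr(filtered, "n_objects")
  stopifnot(n_after <= n_before)
  records <- measure_nuclei(filtered, dapi, gh2ax, config$pixel_pitch)
  attr(records, "stage_counts") <- c(n_foreground_px = sum(mask),
                                     n_components = n_before,
                                     n_nuclei = n_after)
  attr(records, "labels") <- filtered
  records
}

#' Summarize nucleus records per well
#'
#' Sums nucleus counts over a well's fields, normalizes counts to the mean
#' of the plate's control wells, and averages the per-nucleus mean
#' gamma-H2AX over all nuclei in the well. Wells whose total count falls
#' below `min_nuclei_floor` keep their count but have the gamma-H2AX mean
#' reported as missing (too few nuclei for a stable intensity average).
#'
#' @param records Tibble of per-nucleus records with columns `well`,
#'   `field` and `mean_gh2ax` (e.g. rows of [run_field()] outputs bound
#'   together).
#' @param layout The plate's [plate_layout()].
#' @param min_nuclei_floor Minimum nuclei per well for the gamma-H2AX
#'   average (default 50).
#' @return Tibble with one row per layout well: `well`, `condition`,
#'   `concentration_uM`, `is_control`, `n_nuclei`, `n_nuclei_pct_control`,
#'   `mean_of_mean_gh2ax`, `n_fields_used`.
#' @export
summarize_wells <- function(records, layout, min_nuclei_floor = 50L) {
  stopifnot(inherits(layout, "plate_layout"))
  if (nrow(records) > 0 && !all(records$well %in% layout$wells$well)) {
    stop("records reference wells absent from the layout.", call. = FALSE)
  }
  per_well <- records |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(n_nuclei = dplyr::n(),
                     mean_of_mean_gh2ax = mean(.data$mean_gh2ax),
                     .groups = "drop")
  out <- layout$wells |>
    dplyr::left_join(per_well, by = "well") |>
    dplyr::mutate(
      n_nuclei = dplyr::coalesce(.data$n_nuclei, 0L),
      mean_of_mean_gh2ax = ifelse(.data$n_nuclei >= min_nuclei_floor,
                                  .data$mean_of_mean_gh2ax, NA_real_),
      n_fields_used = layout$fields_per_well)
  control_mean <- mean(out$n_nuclei[out$is_control])
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("control wells contain no nuclei; cannot normalize.", call. = FALSE)
  }
  out$n_nuclei_pct_control <- normalize_to_control(out$n_nuclei,
    out$n_nuclei[out$is_control])
  dplyr::select(out, "well", "condition", "concentration_uM", "is_control",
                "n_nuclei", "n_nuclei_pct_control", "mean_of_mean_gh2ax",
                "n_fields_used")
}

#' Run a full multi-plate experiment
#'
#' Processes every field of every simulated plate through [run_field()],
#' summarizes wells within each plate (normalizing to that plate's own
#' controls before pooling, so plate-to-plate gain differences cancel),
#' pools replicate plates per condition and concentration (mean +/- SEM),
#' and fits one four-parameter logistic curve per treated condition on the
#' replicate-resolved normalized counts.
#'
#' @param plates List of plate field tables from [generate_dose_plate()]
#'   (each carrying its layout as an attribute).
#' @param model A `pixel_classifier`.
#' @param config A [pipeline_config()].
#' @param min_nuclei_floor See [summarize_wells()].
#' @param fit Fit dose-response curves per condition (default TRUE).
#' @return An `hcs_experiment`: list with tibbles `nuclei`, `wells`,
#'   `pooled`, the named list `fits` of `dr_fit` objects, the tibble
#'   `fit_summary` (one [glance()] row per condition) and `config_hash`.
#' @export
run_experiment <- function(plates, model, config = pipeline_config(),
                           min_nuclei_floor = 50L, fit = TRUE) {
  stopifnot(length(plates) >= 1L)
  layouts <- lapply(plates, attr, "layout")
  if (any(vapply(layouts, is.null, logical(1)))) {
    stop("each plate table must carry its layout as attribute 'layout'.",
         call. = FALSE)
  }
  pitches <- vapply(layouts, function(l) l$pixel_pitch, numeric(1))
  if (length(unique(pitches)) != 1L) {
    stop("pooled plates must share a single pixel pitch.", call. = FALSE)
  }
  nuclei <- vector("list", length(plates))
  wells <- vector("list", length(plates))
  for (i in seq_along(plates)) {
    pl <- plates[[i]]
    recs <- purrr::pmap(
      list(pl$scene, pl$well, pl$field),
      function(scene, well, field) {
        r <- run_field(scene$dapi, scene$gh2ax, model, config)
        dplyr::mutate(r, plate = layouts[[i]]$plate_id, well = well,
                      field = field, .before = 1L)
      })
    nuclei[[i]] <- dplyr::bind_rows(recs)
    wells[[i]] <- summarize_wells(nuclei[[i]], layouts[[i]],
                                  min_nuclei_floor) |>
      dplyr::mutate(plate = layouts[[i]]$plate_id, .before = 1L)
  }
  nuclei <- dplyr::bind_rows(nuclei) |>
    dplyr::mutate(config_hash = config$hash)
  wells <- dplyr::bind_rows(wells) |>
    dplyr::mutate(config_hash = config$hash)
  pooled <- wells |>
    dplyr::group_by(.data$condition, .data$concentration_uM, .data$is_control) |>
    dplyr::summarise(
      n_plates = dplyr::n(),
      mean_pct_control = mean(.data$n_nuclei_pct_control),
      sem_pct_control = stats::sd(.data$n_nuclei_pct_control) /
        sqrt(dplyr::n()),
      .groups = "drop")
  fits <- list()
  fit_summary <- tibble::tibble()
  if (fit) {
    treated <- dplyr::filter(wells, !.data$is_control)
    for (cond in unique(treated$condition)) {
      d <- dplyr::filter(treated, .data$condition == cond)
      if (length(unique(d$concentration_uM)) >= 4L) {
        fits[[cond]] <- fit_4pl(d, concentration = concentration_uM,
                                response = n_nuclei_pct_control)
      }
    }
    if (length(fits) > 0) {
      fit_summary <- dplyr::bind_rows(lapply(fits, glance), .id = "condition")
    }
  }
  structure(list(nuclei = nuclei, wells = wells, pooled = pooled,
                 fits = fits, fit_summary = fit_summary,
                 config_hash = config$hash),
            class = "hcs_experiment")
}

#' Write experiment results as CSV
#'
#' Emits the per-nucleus, per-well and fit-summary tables. Given identical
#' seeds, inputs and configuration, the written files are byte-identical
#' across runs.
#'
#' @param result An `hcs_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_csvs <- function(result, dir) {
  stopifnot(inherits(result, "hcs_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("nuclei.csv", "wells.csv", "fits.csv"))
  utils::write.csv(result$nuclei, paths[1], row.names = FALSE)
  utils::write.csv(result$wells, paths[2], row.names = FALSE)
  utils::write.csv(result$fit_summary, paths[3], row.names = FALSE)
  invisible(paths)
}

#' @export
print.hcs_experiment <- function(x, ...) {
  cat(sprintf("<hcs_experiment> %d nuclei, %d wells, %d fitted condition(s)\n",
              nrow(x$nuclei), nrow(x$wells), length(x$fits)))
  invisible(x)
}
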