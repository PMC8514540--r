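#' Parameters of a synthetic two-channel microscopy field
#'
#' Describes the generative model for one simulated field: ellipse-shaped
#' nuclei of realistic size placed (by default without overlap) on a dark
#' background, a DAPI channel in which every nucleus is strictly brighter
#' than the background, a gamma-H2AX channel rendered only inside nuclei
#' (basal level, with a "positive" subpopulation at `gh2ax_positive_gain`
#' times the basal level), optical blur by a Gaussian point-spread function,
#' and mixed Poisson-Gaussian camera noise, quantized to the 16-bit range.
#'
#' @param field_shape Field size in pixels, `c(rows, cols)`.
#' @param pixel_pitch Micrometres per pixel side (default 0.3225, at which
#'   200 px corresponds to 20.8 square micrometres).
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_axes_range Range of ellipse semi-axes in micrometres.
#' @param dapi_intensity_range Range of per-nucleus DAPI fill intensities
#'   (arbitrary camera units).
#' @param dapi_background DAPI background level; must be below the dimmest
#'   nucleus.
#' @param gh2ax_basal Basal mean nuclear gamma-H2AX intensity.
#' @param gh2ax_background Extranuclear gamma-H2AX level (near zero).
#' @param gh2ax_positive_fraction Fraction of nuclei with elevated
#'   gamma-H2AX, in [0, 1].
#' @param gh2ax_positive_gain Multiplicative factor (> 1) over the basal
#'   nuclear gamma-H2AX for positive nuclei.
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 disables blur).
#' @param noise_gaussian_sd Additive Gaussian read-noise SD (0 disables).
#' @param noise_poisson_scale Photon-noise scale: the blurred signal times
#'   this factor is Poisson-sampled and rescaled (0 disables).
#' @param overlap_allowed Allow nuclei to overlap (later nuclei occlude
#'   earlier ones in the label map).
#' @param min_separation_px Minimum pixel gap enforced between nuclei when
#'   overlap is not allowed.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `scene_params` object.
#' @export
scene_params <- function(field_shape = c(200L, 200L),
                         pixel_pitch = 0.3225,
                         n_nuclei = 13L,
                         nucleus_axes_range = c(3.5, 6.5),
                         dapi_intensity_range = c(9000, 15000),
                         dapi_background = 300,
                         gh2ax_basal = 600,
                         gh2ax_background = 50,
                         gh2ax_positive_fraction = 0.2,
                         gh2ax_positive_gain = 5,
                         psf_sigma = 1,
                         noise_gaussian_sd = 40,
                         noise_poisson_scale = 0.05,
                         overlap_allowed = FALSE,
                         min_separation_px = 4L,
                         seed = 1L) {
  p <- list(field_shape = as.integer(field_shape), pixel_pitch = pixel_pitch,
            n_nuclei = as.integer(n_nuclei),
            nucleus_axes_range = nucleus_axes_range,
            dapi_intensity_range = dapi_intensity_range,
            dapi_background = dapi_background,
            gh2ax_basal = gh2ax_basal, gh2ax_background = gh2ax_background,
            gh2ax_positive_fraction = gh2ax_positive_fraction,
            gh2ax_positive_gain = gh2ax_positive_gain,
            psf_sigma = psf_sigma, noise_gaussian_sd = noise_gaussian_sd,
            noise_poisson_scale = noise_poisson_scale,
            overlap_allowed = isTRUE(overlap_allowed),
            min_separation_px = as.integer(min_separation_px),
            seed = as.integer(seed))
  if (length(p$field_shape) != 2L || any(p$field_shape <= 0L)) {
    stop("`field_shape` must be two positive integers.", call. = FALSE)
  }
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive.", call. = FALSE)
  if (p$n_nuclei < 0L) stop("`n_nuclei` must be >= 0.", call. = FALSE)
  for (f in c("nucleus_axes_range", "dapi_intensity_range")) {
    if (length(p[[f]]) != 2L || p[[f]][1] > p[[f]][2] || any(p[[f]] <= 0)) {
      stop(sprintf("`%s` must be (min, max) with 0 < min <= max.", f),
           call. = FALSE)
    }
  }
  if (gh2ax_positive_fraction < 0 || gh2ax_positive_fraction > 1) {
    stop("`gh2ax_positive_fraction` must lie in [0, 1].", call. = FALSE)
  }
  if (gh2ax_positive_gain <= 1) {
    stop("`gh2ax_positive_gain` must exceed 1.", call. = FALSE)
  }
  if (dapi_background >= p$dapi_intensity_range[1]) {
    stop("`dapi_background` must be below the dimmest nucleus intensity.",
         call. = FALSE)
  }
  max_axis_px <- p$nucleus_axes_range[2] / pixel_pitch
  if (p$n_nuclei > 0L && 2 * max_axis_px + 4 > min(p$field_shape)) {
    stop("`nucleus_axes_range`: the largest nucleus does not fit in `field_shape`.",
         call. = FALSE)
  }
  structure(p, class = "scene_params")
}

# pixel set of an ellipse (semi-axes in px, orientation in radians) within
# the field; returns linear indices (column-major)
ellipse_pixels <- function(cy, cx, a, b, theta, nr, nc) {
  r_ext <- max(a, b)
  rows <- max(1L, floor(cy - r_ext)):min(nr, ceiling(cy + r_ext))
  cols <- max(1L, floor(cx - r_ext)):min(nc, ceiling(cx + r_ext))
  dy <- rows - cy
  dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (y * ct + x * st) / a)
  v <- outer(dy, dx, function(y, x) (-y * st + x * ct) / b)
  inside <- which(u^2 + v^2 <= 1)
  if (length(inside) == 0L) return(integer(0))
  ri <- rows[((inside - 1L) %% length(rows)) + 1L]
  ci <- cols[((inside - 1L) %/% length(rows)) + 1L]
  (ci - 1L) * nr + ri
}

#' Generate one synthetic two-channel field with exact ground truth
#'
#' Renders the nuclei into the label map first (exact ground truth), then
#' applies the optical and camera model (blur, Poisson, Gaussian noise,
#' 16-bit quantization) to the intensity channels only.
#'
#' @param params A [scene_params()].
#' @return A `ground_truth_scene`: list with integer-valued intensity
#'   matrices `dapi` and `gh2ax`, the `true_labels` matrix, the
#'   `nuclei_truth` tibble (label, center, semi-axes, orientation,
#'   gamma-H2AX status and true pre-noise mean), and `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$field_shape[1]; nc <- params$field_shape[2]
  withr::with_seed(params$seed, {
    labels <- matrix(0L, nr, nc)
    n <- params$n_nuclei
    truth <- tibble::tibble(
      label = integer(0), center_row = numeric(0), center_col = numeric(0),
      axis_a_um = numeric(0), axis_b_um = numeric(0), orientation = numeric(0),
      is_gh2ax_positive = logical(0), true_mean_gh2ax = numeric(0),
      dapi_intensity = numeric(0))
    occupied <- matrix(FALSE, nr, nc)
    gap <- params$min_separation_px / 2
    if (n > 0L) {
      max_axis_px <- params$nucleus_axes_range[2] / params$pixel_pitch
      margin <- max_axis_px + 2
      placed <- 0L
      attempts <- 0L
      max_attempts <- 500L * n
      rows_t <- numeric(n); cols_t <- numeric(n)
      a_t <- numeric(n); b_t <- numeric(n); th_t <- numeric(n)
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop(sprintf(
            "could not place %d non-overlapping nuclei in a %d x %d field after %d attempts; reduce `n_nuclei` or allow overlap.",
            n, nr, nc, max_attempts), call. = FALSE)
        }
        cy <- stats::runif(1, 1 + margin, nr - margin)
        cx <- stats::runif(1, 1 + margin, nc - margin)
        ab <- stats::runif(2, params$nucleus_axes_range[1],
                           params$nucleus_axes_range[2]) / params$pixel_pitch
        theta <- stats::runif(1, 0, pi)
        if (!params$overlap_allowed) {
          dil <- ellipse_pixels(cy, cx, ab[1] + gap, ab[2] + gap, theta, nr, nc)
          if (any(occupied[dil])) next
          occupied[dil] <- TRUE
        }
        placed <- placed + 1L
        px <- ellipse_pixels(cy, cx, ab[1], ab[2], theta, nr, nc)
        labels[px] <- placed
        rows_t[placed] <- cy; cols_t[placed] <- cx
        a_t[placed] <- ab[1] * params$pixel_pitch
        b_t[placed] <- ab[2] * params$pixel_pitch
        th_t[placed] <- theta
      }
      is_pos <- stats::runif(n) < params$gh2ax_positive_fraction
      dapi_i <- round(stats::runif(n, params$dapi_intensity_range[1],
                                   params$dapi_intensity_range[2]))
      mean_g <- round(params$gh2ax_basal *
                        ifelse(is_pos, params$gh2ax_positive_gain, 1))
      truth <- tibble::tibble(
        label = seq_len(n), center_row = rows_t, center_col = cols_t,
        axis_a_um = a_t, axis_b_um = b_t, orientation = th_t,
        is_gh2ax_positive = is_pos, true_mean_gh2ax = mean_g,
        dapi_intensity = dapi_i)
    }

    dapi <- matrix(params$dapi_background, nr, nc)
    gh2ax <- matrix(params$gh2ax_background, nr, nc)
    if (n > 0L) {
      pos <- labels > 0L
      dapi[pos] <- truth$dapi_intensity[labels[pos]]
      gh2ax[pos] <- truth$true_mean_gh2ax[labels[pos]]
    }
    degrade <- function(img) {
      if (params$psf_sigma > 0) img <- gaussian_smooth(img, params$psf_sigma)
      if (params$noise_poisson_scale > 0) {
        img <- matrix(stats::rpois(length(img),
                                   pmax(img, 0) * params$noise_poisson_scale) /
                        params$noise_poisson_scale, nr, nc)
      }
      if (params$noise_gaussian_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img),
                                         sd = params$noise_gaussian_sd), nr, nc)
      }
      matrix(pmin(pmax(round(img), 0), 65535), nr, nc)
    }
    dapi <- degrade(dapi)
    gh2ax <- degrade(gh2ax)
    structure(list(dapi = dapi, gh2ax = gh2ax, true_labels = labels,
                   nuclei_truth = truth, params = params),
              class = "ground_truth_scene")
  })
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("<ground_truth_scene> %d x %d px, %d nuclei (%d gamma-H2AX positive), seed %d\n",
              nrow(x$dapi), ncol(x$dapi), nrow(x$nuclei_truth),
              sum(x$nuclei_truth$is_gh2ax_positive), x$params$seed))
  invisible(x)
}

#' True dose-response curve for simulated plates
#'
#' Defines the expected per-field nuclei count as a four-parameter logistic
#' function of the reference-compound concentration, plus the concentration
#' at which gamma-H2AX activation switches on.
#'
#' @param pIC50 True potency (negative log10 molar IC50).
#' @param bottom_pct Bottom plateau in percent of the zero-dose count.
#' @param hill Hill slope (positive for a decreasing count with dose).
#' @param top_count Expected nuclei per field at zero dose.
#' @param gh2ax_threshold_uM Concentration (micromolar) at or above which
#'   nuclei become gamma-H2AX "damaged" (default `Inf`: never).
#' @param damaged_positive_fraction `gh2ax_positive_fraction` used for wells
#'   at or above the threshold.
#' @return A `dose_response_truth` object.
#' @export
dose_response_truth <- function(pIC50, bottom_pct = 0, hill = 1, top_count = 20,
                                gh2ax_threshold_uM = Inf,
                                damaged_positive_fraction = 0.9) {
  stopifnot(is.finite(pIC50), bottom_pct >= 0, bottom_pct < 100,
            hill > 0, top_count > 0)
  structure(list(pIC50 = pIC50, bottom_pct = bottom_pct, hill = hill,
                 top_count = top_count,
                 gh2ax_threshold_uM = gh2ax_threshold_uM,
                 damaged_positive_fraction = damaged_positive_fraction),
            class = "dose_response_truth")
}

#' Expected nuclei count at a concentration
#'
#' Evaluates the generating four-parameter logistic curve: the zero-dose
#' asymptote (`top_count`) for controls, `top_count * bottom_pct / 100` at
#' saturating dose.
#'
#' @param truth A [dose_response_truth()].
#' @param concentration_uM Concentration(s) in micromolar (0 = control).
#' @return Expected count(s) per field.
#' @export
expected_nuclei_count <- function(truth, concentration_uM) {
  stopifnot(inherits(truth, "dose_response_truth"))
  if (any(!is.finite(concentration_uM)) || any(concentration_uM < 0)) {
    stop("concentrations must be finite and non-negative.", call. = FALSE)
  }
  l50 <- 6 - truth$pIC50
  r <- ifelse(concentration_uM == 0, 100,
              truth$bottom_pct + (100 - truth$bottom_pct) /
                (1 + 10^(truth$hill * (log10(pmax(concentration_uM, 1e-300)) - l50))))
  truth$top_count * r / 100
}

#' Plate layout
#'
#' Maps wells to treatment conditions and concentrations. At least one
#' control well is required: it anchors the within-plate normalization.
#'
#' @param plate_id Plate identifier.
#' @param wells Tibble with columns `well`, `condition`,
#'   `concentration_uM` and logical `is_control` (controls carry
#'   concentration 0).
#' @param fields_per_well Imaging fields acquired per well.
#' @param pixel_pitch Micrometres per pixel side.
#' @return A `plate_layout` object.
#' @export
plate_layout <- function(plate_id, wells, fields_per_well = 2L,
                         pixel_pitch = 0.3225) {
  need <- c("well", "condition", "concentration_uM", "is_control")
  if (!all(need %in% names(wells))) {
    stop(sprintf("`wells` must have columns: %s.", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!any(wells$is_control)) {
    stop("layout must contain at least one control well.", call. = FALSE)
  }
  if (anyDuplicated(wells$well)) {
    stop("well identifiers must be unique.", call. = FALSE)
  }
  structure(list(plate_id = plate_id, wells = tibble::as_tibble(wells),
                 fields_per_well = as.integer(fields_per_well),
                 pixel_pitch = pixel_pitch),
            class = "plate_layout")
}

#' Helper layout for a dilution series plus controls
#'
#' @param plate_id Plate identifier.
#' @param condition Condition name.
#' @param concentrations_uM Vector of treated concentrations (micromolar).
#' @param n_control_wells Number of vehicle control wells.
#' @param fields_per_well,pixel_pitch See [plate_layout()].
#' @return A `plate_layout`.
#' @export
dilution_layout <- function(plate_id, condition, concentrations_uM,
                            n_control_wells = 2L, fields_per_well = 2L,
                            pixel_pitch = 0.3225) {
  wells <- tibble::tibble(
    well = c(sprintf("C%02d", seq_len(n_control_wells)),
             sprintf("W%02d", seq_along(concentrations_uM))),
    condition = c(rep("control", n_control_wells),
                  rep(condition, length(concentrations_uM))),
    concentration_uM = c(rep(0, n_control_wells), concentrations_uM),
    is_control = c(rep(TRUE, n_control_wells),
                   rep(FALSE, length(concentrations_uM))))
  plate_layout(plate_id, wells, fields_per_well, pixel_pitch)
}

# deterministic per-field seed below 2^31
derive_seed <- function(base, well_index, field) {
  as.integer((as.double(base) + 7919 * well_index + 104729 * field) %% 2147483647)
}

#' Simulate a full dose plate
#'
#' For every well the expected nuclei count is the generating 4PL evaluated
#' at the well's concentration (controls sit at the zero-dose asymptote);
#' the realized per-field count is Poisson-sampled. Wells at or above the
#' gamma-H2AX activation threshold get the "damaged" positive fraction.
#'
#' @param layout A [plate_layout()].
#' @param dr_truth A [dose_response_truth()].
#' @param params A [scene_params()] template; its `seed` seeds the plate and
#'   per-field seeds are derived from it deterministically.
#' @return A tibble with one row per field: `plate`, `well`, `condition`,
#'   `concentration_uM`, `is_control`, `field`, `n_nuclei_true` and a
#'   `scene` list-column of `ground_truth_scene`s. The layout is attached as
#'   attribute `layout`.
#' @export
generate_dose_plate <- function(layout, dr_truth, params = scene_params()) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(dr_truth, "dose_response_truth"),
            inherits(params, "scene_params"))
  wells <- layout$wells
  if (any(!is.finite(wells$concentration_uM)) || any(wells$concentration_uM < 0)) {
    stop("layout references a concentration outside the dose-response truth coverage (must be finite and >= 0).",
         call. = FALSE)
  }
  params <- scene_params_with(params, pixel_pitch = layout$pixel_pitch)
  rows <- vector("list", nrow(wells) * layout$fields_per_well)
  k <- 0L
  for (w in seq_len(nrow(wells))) {
    conc <- wells$concentration_uM[w]
    expected <- expected_nuclei_count(dr_truth, conc)
    frac <- if (conc >= dr_truth$gh2ax_threshold_uM) {
      dr_truth$damaged_positive_fraction
    } else params$gh2ax_positive_fraction
    for (f in seq_len(layout$fields_per_well)) {
      fseed <- derive_seed(params$seed, w, f)
      n_true <- withr::with_seed(fseed, stats::rpois(1L, expected))
      p <- scene_params_with(params, n_nuclei = n_true,
                             gh2ax_positive_fraction = frac,
                             seed = derive_seed(fseed, 0L, 1L))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        plate = layout$plate_id, well = wells$well[w],
        condition = wells$condition[w], concentration_uM = conc,
        is_control = wells$is_control[w], field = f,
        n_nuclei_true = n_true, scene = list(generate_scene(p)))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "layout") <- layout
  out
}

# rebuild scene_params with selected fields replaced (revalidates)
scene_params_with <- function(params, ...) {
  upd <- list(...)
  p <- unclass(params)
  p[names(upd)] <- upd
  do.call(scene_params, p)
}

#' Write a scene to disk as TIFF + truth CSV
#'
#' Writes one 16-bit grayscale TIFF per channel named
#' `<field>_dapi.tif` / `<field>_gh2ax.tif`, a 16-bit label TIFF
#' `<field>_labels.tif`, and a ground-truth CSV. Requires the `tiff`
#' package.
#'
#' @param scene A `ground_truth_scene`.
#' @param dir Output directory (created if needed).
#' @param field Field name used as the file stem.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, field = "f01") {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required to write TIFF files.", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(field, c("_dapi.tif", "_gh2ax.tif",
                                          "_labels.tif", "_truth.csv")))
  tiff::writeTIFF(scene$dapi / 65535, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(scene$gh2ax / 65535, paths[2], bits.per.sample = 16L)
  tiff::writeTIFF(scene$true_labels / 65535, paths[3], bits.per.sample = 16L)
  utils::write.csv(scene$nuclei_truth, paths[4], row.names = FALSE)
  invisible(paths)
}
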