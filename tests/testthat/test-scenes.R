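test_that("an empty scene is pure background noise", {
  p <- scene_params(n_nuclei = 0L, seed = 4L)
  sc <- generate_scene(p)
  expect_true(all(sc$true_labels == 0L))
  expect_identical(nrow(sc$nuclei_truth), 0L)
  # DAPI fluctuates around the background level, far below any nucleus
  expect_lt(mean(sc$dapi), min(p$dapi_intensity_range) / 2)
})

test_that("identical parameters and seed give bit-identical scenes", {
  p <- scene_params(seed = 123L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$dapi, b$dapi)
  expect_identical(a$gh2ax, b$gh2ax)
  expect_identical(a$true_labels, b$true_labels)
  expect_identical(a$nuclei_truth, b$nuclei_truth)
  c <- generate_scene(scene_params(seed = 124L))
  expect_false(identical(a$dapi, c$dapi))
})

test_that("non-overlap placement yields the requested disjoint nuclei", {
  p <- scene_params(field_shape = c(300L, 300L), n_nuclei = 50L,
                    nucleus_axes_range = c(2.5, 3.5),
                    overlap_allowed = FALSE, seed = 7L)
  sc <- generate_scene(p)
  labs <- setdiff(unique(as.integer(sc$true_labels)), 0L)
  expect_length(labs, 50L)
  # label/truth bijection
  expect_setequal(labs, sc$nuclei_truth$label)
  expect_identical(nrow(sc$nuclei_truth), 50L)
  # every label forms one connected object (disjointness is inherent to a
  # single-valued label map; connectivity guards against fragmented renders)
  cc <- label_components(sc$true_labels > 0L, 8)
  expect_identical(attr(cc, "n_objects"), 50L)
})

test_that("scene intensities are quantized to the 16-bit range", {
  sc <- generate_scene(scene_params(seed = 9L))
  for (ch in list(sc$dapi, sc$gh2ax)) {
    expect_true(all(ch >= 0 & ch <= 65535))
    expect_true(all(ch == round(ch)))
  }
})

test_that("positive nuclei carry the configured gamma-H2AX gain pre-noise", {
  p <- scene_params(field_shape = c(160L, 160L), n_nuclei = 8L,
                    gh2ax_positive_fraction = 0.5, psf_sigma = 0,
                    noise_gaussian_sd = 0, noise_poisson_scale = 0, seed = 31L)
  sc <- generate_scene(p)
  truth <- sc$nuclei_truth
  expect_true(any(truth$is_gh2ax_positive) && any(!truth$is_gh2ax_positive))
  expect_equal(truth$true_mean_gh2ax[truth$is_gh2ax_positive],
               rep(round(p$gh2ax_basal * p$gh2ax_positive_gain),
                   sum(truth$is_gh2ax_positive)))
  expect_equal(truth$true_mean_gh2ax[!truth$is_gh2ax_positive],
               rep(round(p$gh2ax_basal), sum(!truth$is_gh2ax_positive)))
  # pre-noise DAPI foreground strictly brighter than background
  expect_gt(min(sc$dapi[sc$true_labels > 0]), max(sc$dapi[sc$true_labels == 0]))
})

test_that("degenerate geometry and invalid parameters are rejected", {
  expect_error(scene_params(field_shape = c(30L, 30L),
                            nucleus_axes_range = c(5, 8)),
               "nucleus_axes_range")
  expect_error(scene_params(gh2ax_positive_fraction = 1.2), "0, 1")
  expect_error(scene_params(nucleus_axes_range = c(5, 3)), "min <= max")
  expect_error(scene_params(dapi_background = 20000), "below")
  expect_error(scene_params(gh2ax_positive_gain = 0.5), "exceed 1")
})

test_that("expected counts follow the generating 4PL", {
  truth <- dose_response_truth(pIC50 = 4.5, bottom_pct = 0, hill = 1,
                               top_count = 30)
  # zero dose sits at the top asymptote
  expect_equal(expected_nuclei_count(truth, 0), 30)
  # at the IC50 with bottom 0 the count halves
  expect_equal(expected_nuclei_count(truth, pIC50_to_IC50(4.5)), 15)
  # monotone non-increasing in concentration
  conc <- 10^seq(-3, 3, length.out = 25)
  counts <- expected_nuclei_count(truth, conc)
  expect_true(all(diff(counts) <= 0))
  truth2 <- dose_response_truth(pIC50 = 5, bottom_pct = 40, hill = 2,
                                top_count = 20)
  expect_true(all(diff(expected_nuclei_count(truth2, conc)) <= 0))
  expect_equal(expected_nuclei_count(truth2, 1e9), 8, tolerance = 1e-3)
})

test_that("dose plates honour layout, seed determinism and gamma-H2AX switch", {
  lay <- dilution_layout("P1", "drug", c(10, 1, 0.1), n_control_wells = 1L,
                         fields_per_well = 2L)
  truth <- dose_response_truth(pIC50 = 6, bottom_pct = 0, hill = 1,
                               top_count = 4, gh2ax_threshold_uM = 5,
                               damaged_positive_fraction = 0.9)
  sp <- scene_params(field_shape = c(192L, 192L), seed = 88L)
  pl1 <- generate_dose_plate(lay, truth, sp)
  pl2 <- generate_dose_plate(lay, truth, sp)
  expect_identical(lapply(pl1$scene, `[[`, "dapi"),
                   lapply(pl2$scene, `[[`, "dapi"))
  expect_equal(nrow(pl1), 4L * 2L)
  # wells at/above the activation threshold get the damaged fraction
  fracs <- vapply(seq_len(nrow(pl1)), function(i) {
    pl1$scene[[i]]$params$gh2ax_positive_fraction
  }, numeric(1))
  expect_true(all(fracs[pl1$concentration_uM >= 5] == 0.9))
  expect_true(all(fracs[pl1$concentration_uM < 5] == sp$gh2ax_positive_fraction))
  bad_lay <- lay
  bad_lay$wells$concentration_uM[2] <- NA
  expect_error(generate_dose_plate(bad_lay, truth, sp), "concentration")
})

test_that("refitting per-well counts from a dose plate recovers the truth", {
  truth <- dose_response_truth(pIC50 = 5.5, bottom_pct = 0, hill = 2,
                               top_count = 25)
  conc <- 100 / 6^(0:7)
  counts <- lapply(1:3, function(p) {
    lay <- dilution_layout(sprintf("P%d", p), "drug", conc,
                           n_control_wells = 2L, fields_per_well = 3L)
    # count-level view of the plate: Poisson per field around the 4PL
    withr::with_seed(600 + p, {
      well_counts <- vapply(seq_len(nrow(lay$wells)), function(w) {
        sum(stats::rpois(lay$fields_per_well,
                         expected_nuclei_count(truth,
                                               lay$wells$concentration_uM[w])))
      }, numeric(1))
      pct <- normalize_to_control(well_counts, well_counts[lay$wells$is_control])
      tibble::tibble(concentration_uM = lay$wells$concentration_uM,
                     response_pct = pct,
                     is_control = lay$wells$is_control)
    })
  })
  d <- dplyr::filter(dplyr::bind_rows(counts), !is_control)
  fit <- fit_4pl(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$pIC50 - 5.5), 0.1)
})

test_that("scenes round-trip to TIFF and truth CSV on disk", {
  skip_if_not_installed("tiff")
  sc <- generate_scene(scene_params(field_shape = c(96L, 96L), n_nuclei = 3L,
                                    seed = 12L))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, field = "f01")
  expect_true(all(file.exists(paths)))
  back <- round(tiff::readTIFF(paths[1]) * 65535)
  expect_equal(back, unclass(sc$dapi), tolerance = 1e-9,
               ignore_attr = TRUE)
  truth <- utils::read.csv(paths[4])
  expect_equal(nrow(truth), 3L)
})
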