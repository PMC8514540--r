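test_that("binarize applies an inclusive threshold", {
  p <- matrix(c(0, 0.25, 0.5, 0.75, 1, 0.4999), 2, 3)
  m <- binarize(p, 0.5)
  expect_identical(m, matrix(c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE), 2, 3))
  expect_false(any(binarize(matrix(0, 3, 3))))
  # a 0/1 indicator map reproduces itself
  gt <- matrix(sample(c(0, 1), 64, replace = TRUE), 8)
  expect_identical(binarize(gt, 0.5), gt == 1)
  expect_error(binarize(p, 0), "strictly between")
  expect_error(binarize(p, 1), "strictly between")
  expect_error(binarize(matrix(2, 2, 2)), "0, 1")
})

test_that("connectivity decides whether diagonal blobs merge", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # touch only diagonally
  expect_identical(attr(label_components(m, 8), "n_objects"), 1L)
  expect_identical(attr(label_components(m, 4), "n_objects"), 2L)
  expect_error(label_components(m, 6), "4 or 8")
})

test_that("checkerboard under 4-connectivity is all singletons", {
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  lab <- label_components(cb, 4)
  expect_identical(attr(lab, "n_objects"), 8L)
  expect_true(same_partition(lab, flood_fill_labels(cb, 4L)))
})

test_that("labeling matches a brute-force flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(runif(32 * 32) < 0.45, 32)
    for (conn in c(4L, 8L)) {
      lab <- label_components(m, conn)
      oracle <- flood_fill_labels(m, conn)
      expect_true(same_partition(lab, oracle))
      expect_identical(attr(lab, "n_objects"), max(oracle))
      # labels are consecutive 1..K
      expect_setequal(unique(as.integer(lab)), 0:max(oracle))
    }
  }
})

test_that("empty masks label cleanly", {
  lab <- label_components(matrix(FALSE, 6, 6))
  expect_identical(attr(lab, "n_objects"), 0L)
  expect_true(all(lab == 0L))
})

test_that("size filter keeps areas at or above the cutoff only", {
  # four horizontal bars of areas 150, 199, 200, 250 in separate rows
  m <- matrix(FALSE, 9, 260)
  areas <- c(150L, 199L, 200L, 250L)
  for (i in seq_along(areas)) m[2 * i, seq_len(areas[i])] <- TRUE
  lab <- label_components(m, 8)
  filt <- filter_small(lab, 200)
  surv_areas <- sort(tabulate(filt[filt > 0]))
  expect_identical(surv_areas, c(200L, 250L))
  # survivors relabeled consecutively preserving order
  expect_identical(sort(unique(as.integer(filt))), 0:2)

  expect_identical(unclass(filter_small(lab, 0))[, ], unclass(lab)[, ])
  expect_error(filter_small(lab, -5), "non-negative")
})

test_that("size filter is idempotent and monotone in the threshold", {
  set.seed(3)
  m <- matrix(runif(64 * 64) < 0.35, 64)
  lab <- label_components(m, 8)
  for (thr in c(0, 3, 10, 40)) {
    f1 <- filter_small(lab, thr)
    expect_identical(filter_small(f1, thr)[, ], f1[, ])
    # survivor count equals exhaustive enumeration of component areas
    areas <- tabulate(lab[lab > 0])
    expect_identical(attr(f1, "n_objects"), sum(areas >= thr))
  }
  counts <- sapply(c(0, 2, 5, 10, 20, 50), function(thr) {
    attr(filter_small(lab, thr), "n_objects")
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("pixel areas convert to square micrometres by the pitch squared", {
  expect_equal(area_to_um2(200, 0.3225), 20.8, tolerance = 5e-4)
  expect_identical(area_to_um2(0, 0.3225), 0)
  expect_identical(area_to_um2(1, 1), 1)
  expect_error(area_to_um2(10, 0), "positive")
})

test_that("nucleus measurements are exact on uniform regions", {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:6] <- 1L  # 10 pixels
  dapi <- matrix(3, 6, 6)
  gh2ax <- matrix(0, 6, 6); gh2ax[lab == 1L] <- 7
  rec <- measure_nuclei(lab, dapi, gh2ax, pixel_pitch = 0.5)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$area_px, 10L)
  expect_equal(rec$area_um2, 10 * 0.25)
  expect_equal(rec$mean_gh2ax, 7)
  expect_equal(rec$total_gh2ax, 70)
  expect_equal(rec$mean_dapi, 3)
  expect_equal(rec$centroid_row, 2.5)
  expect_equal(rec$centroid_col, 4)

  empty <- measure_nuclei(matrix(0L, 4, 4), matrix(1, 4, 4), matrix(1, 4, 4))
  expect_identical(nrow(empty), 0L)
  expect_error(measure_nuclei(lab, dapi, matrix(0, 3, 3)), "same shape")
})

test_that("totals satisfy mean x area and are additive under splits", {
  set.seed(9)
  img <- matrix(runif(40 * 40, 0, 100), 40)
  m <- matrix(runif(40 * 40) < 0.3, 40)
  lab <- filter_small(label_components(m, 8), 5)
  rec <- measure_nuclei(lab, img, img)
  expect_equal(rec$total_dapi, rec$mean_dapi * rec$area_px, tolerance = 1e-6)
  # split the first component into two arbitrary halves: totals add up
  px <- which(lab == 1L)
  split_lab <- matrix(0L, 40, 40)
  split_lab[px[seq_len(floor(length(px) / 2))]] <- 1L
  split_lab[px[(floor(length(px) / 2) + 1):length(px)]] <- 2L
  parts <- measure_nuclei(split_lab, img, img)
  expect_equal(sum(parts$total_dapi), rec$total_dapi[1], tolerance = 1e-9)
})

test_that("per-nucleus gamma-H2AX means match generator truth on clean scenes", {
  p <- scene_params(field_shape = c(128L, 128L), n_nuclei = 4L,
                    psf_sigma = 0, noise_gaussian_sd = 0,
                    noise_poisson_scale = 0, seed = 5L)
  sc <- generate_scene(p)
  rec <- measure_nuclei(sc$true_labels, sc$dapi, sc$gh2ax)
  truth <- sc$nuclei_truth
  expect_equal(rec$mean_gh2ax[truth$label], truth$true_mean_gh2ax,
               tolerance = 1e-6)
  expect_equal(rec$mean_dapi[truth$label], truth$dapi_intensity,
               tolerance = 1e-6)
})
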