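test_that("dilution series follow the fold factor and molar ratios", {
  cond <- treatment_condition(c(lomustine = 1), 100, 6, 8)
  ser <- make_dilution_series(cond)
  expect_equal(nrow(ser), 8L)
  expect_equal(ser$concentration_uM[1], 100)
  expect_equal(signif(ser$concentration_uM[2], 3), 16.7)
  expect_equal(ser$concentration_uM, 100 / 6^(0:7))

  flat <- make_dilution_series(treatment_condition(c(a = 1), 10, 1, 5))
  expect_true(all(flat$concentration_uM == 10))

  mix <- treatment_condition(c(lomustine = 1, azacytidine = 0.1), 10, 6, 4)
  sm <- make_dilution_series(mix)
  top <- dplyr::filter(sm, point == 1)
  expect_equal(top$concentration_uM[top$compound == "lomustine"], 10)
  expect_equal(top$concentration_uM[top$compound == "azacytidine"], 1)
  # co-component tracks the reference at the fixed ratio at every point
  ratio <- with(sm, concentration_uM[compound == "azacytidine"] /
                  concentration_uM[compound == "lomustine"])
  expect_equal(ratio, rep(0.1, 4))
  expect_error(treatment_condition(c(a = 1), -5), "positive")
  expect_error(treatment_condition(c(1, 2), 10), "named")
})

test_that("control normalization maps the control mean to exactly 100", {
  expect_equal(normalize_to_control(250, c(250, 250)), 100)
  expect_equal(normalize_to_control(0, c(10, 30)), 0)
  expect_equal(normalize_to_control(c(50, 150), c(100, 100)), c(50, 150))
  ctrl <- c(80, 120, 95)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 100)
  # idempotence: renormalizing normalized data by its own mean-100 control
  v <- normalize_to_control(c(40, 90, 130), ctrl)
  expect_equal(normalize_to_control(v, rep(100, 3)), v)
  expect_error(normalize_to_control(1, c(-5, 5)), "positive")
})

test_that("noise-free 4PL data are recovered to numerical precision", {
  conc <- 100 / 6^(0:7)
  d <- tibble::tibble(concentration_uM = conc,
                      response_pct = fourpl_response(conc, 5, 0, 1))
  fit <- fit_4pl(d)
  expect_true(fit$converged)
  expect_equal(fit$pIC50, 5, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  # fitted curve passes through 50% at the IC50
  mid <- fit$bottom + (fit$top - fit$bottom) / 2
  expect_equal(mid, 50, tolerance = 1e-6)
  expect_equal(fit$IC50_uM, 10, tolerance = 1e-5)
})

test_that("scaling concentrations by 10 shifts pIC50 by exactly -1", {
  conc <- 50 / 6^(0:6)
  y <- fourpl_response(conc, 5.3, 12, 1.4)
  f1 <- fit_4pl(tibble::tibble(concentration_uM = conc, response_pct = y))
  f2 <- fit_4pl(tibble::tibble(concentration_uM = conc * 10, response_pct = y))
  expect_equal(f2$pIC50 - f1$pIC50, -1, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
})

test_that("degenerate inputs are surfaced as status, never fabricated", {
  conc <- 100 / 6^(0:5)
  flat <- tibble::tibble(concentration_uM = conc, response_pct = rep(100, 6))
  f <- fit_4pl(flat)
  expect_false(f$converged)
  expect_match(f$status, "no dose effect")
  expect_true(is.na(f$pIC50))

  expect_error(fit_4pl(tibble::tibble(concentration_uM = c(1, 2, 3),
                                      response_pct = c(90, 50, 10))),
               "4 distinct")
  expect_error(compare_pIC50(f, f), "converged")
})

test_that("zero-dose controls are excluded from the fit", {
  conc <- c(0, 100 / 6^(0:5))
  y <- c(100, fourpl_response(100 / 6^(0:5), 5, 0, 1))
  f <- fit_4pl(tibble::tibble(concentration_uM = conc, response_pct = y))
  expect_equal(f$n_obs, 6L)
  expect_equal(f$pIC50, 5, tolerance = 1e-6)
})

test_that("pIC50 and IC50 interconvert on the molar scale", {
  expect_equal(signif(pIC50_to_IC50(4.50), 3), 31.6)
  expect_equal(pIC50_to_IC50(6), 1)
  expect_equal(pIC50_to_IC50(0), 1e6)
})

test_that("pIC50 comparisons follow the normal z-test identities", {
  conc <- 100 / 6^(0:7)
  d <- withr::with_seed(5L, tibble::tibble(
    concentration_uM = rep(conc, each = 4),
    response_pct = fourpl_response(rep(conc, each = 4), 5, 0, 1) +
      rnorm(32, sd = 3)))
  f <- fit_4pl(d)
  same <- compare_pIC50(f, f)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  # a difference of 1.96 pooled SEs sits at p ~= 0.05
  g <- f
  g$pIC50 <- f$pIC50 + 1.96 * sqrt(2) * f$pIC50_se
  cmp <- compare_pIC50(g, f)
  expect_equal(cmp$p_value, 0.05, tolerance = 1e-3)
})

test_that("a true pIC50 shift of 1 is detected in nearly every simulation", {
  conc <- 100 / 6^(0:7)
  hits <- 0L
  for (s in 1:100) {
    d <- withr::with_seed(4000 + s, {
      cc <- rep(conc, each = 4)
      tibble::tibble(
        concentration_uM = cc,
        response_a = fourpl_response(cc, 5.5, 0, 1) + rnorm(32, sd = 5),
        response_b = fourpl_response(cc, 4.5, 0, 1) + rnorm(32, sd = 5))
    })
    fa <- fit_4pl(d, response = response_a)
    fb <- fit_4pl(d, response = response_b)
    if (fa$converged && fb$converged &&
        compare_pIC50(fa, fb)$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("tidy and glance expose the fit in broom conventions", {
  conc <- 100 / 6^(0:7)
  f <- fit_4pl(tibble::tibble(concentration_uM = conc,
                              response_pct = fourpl_response(conc, 5, 10, 1.2)))
  td <- tidy(f)
  expect_identical(td$term, c("pIC50", "bottom", "hill"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$pIC50, f$pIC50)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
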