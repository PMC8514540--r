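#' Describe a treatment condition
#'
#' A single drug or a fixed-ratio mixture applied as a dilution series. The
#' first component is the reference (for mixtures, the chemotherapy drug):
#' the dose axis is always the reference concentration, and co-components
#' follow at their fixed molar ratio.
#'
#' @param components Named numeric vector of molar ratios, reference first,
#'   e.g. `c(lomustine = 1, azacytidine = 0.1)`.
#' @param top_concentration Highest reference concentration in micromolar.
#' @param dilution_factor Fold dilution between consecutive points
#'   (default 6).
#' @param n_points Number of points in the series.
#' @return A `treatment_condition` object.
#' @export
treatment_condition <- function(components, top_concentration,
                                dilution_factor = 6, n_points = 8L) {
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("`components` must be a named vector of molar ratios.", call. = FALSE)
  }
  if (any(components <= 0)) stop("molar ratios must be positive.", call. = FALSE)
  if (top_concentration <= 0) {
    stop("`top_concentration` must be positive.", call. = FALSE)
  }
  structure(list(components = components,
                 top_concentration = top_concentration,
                 dilution_factor = dilution_factor,
                 n_points = as.integer(n_points)),
            class = "treatment_condition")
}

#' Concentration series for a treatment condition
#'
#' The reference component follows `top / factor^(i-1)` for points
#' i = 1..n; each co-component's series is the reference series scaled by
#' its molar ratio relative to the reference.
#'
#' @param cond A [treatment_condition()].
#' @return A tibble with `point`, `compound`, `molar_ratio`,
#'   `concentration_uM`.
#' @export
make_dilution_series <- function(cond) {
  stopifnot(inherits(cond, "treatment_condition"))
  if (cond$n_points < 2L) stop("`n_points` must be at least 2.", call. = FALSE)
  ref_conc <- cond$top_concentration / cond$dilution_factor^(seq_len(cond$n_points) - 1)
  ref_ratio <- cond$components[[1L]]
  tidyr::crossing(
    point = seq_len(cond$n_points),
    compound = names(cond$components)) |>
    dplyr::mutate(
      molar_ratio = unname(cond$components[.data$compound]),
      concentration_uM = ref_conc[.data$point] * .data$molar_ratio / ref_ratio) |>
    dplyr::arrange(.data$point, match(.data$compound, names(cond$components)))
}

#' Normalize measurements to the plate control
#'
#' Expresses raw measurements as percent of the mean of the negative-control
#' (vehicle) measurements, so the control mean itself maps to exactly 100.
#'
#' @param values Numeric raw measurements.
#' @param control_values Numeric raw control measurements (mean must be
#'   positive).
#' @return `values / mean(control_values) * 100`.
#' @export
normalize_to_control <- function(values, control_values) {
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) {
    stop("control mean must be positive and finite.", call. = FALSE)
  }
  values / m * 100
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `R(c) = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) - log10(IC50))))`
#' on the log10 concentration axis, with the top plateau fixed (data are
#' control-normalized, which pins the top at 100%) and bottom, Hill slope
#' and IC50 free. Zero-dose points are excluded from the fit (they only
#' anchor the normalization). Confidence intervals are asymptotic normal
#' intervals from the fit covariance. Non-convergence — including data with
#' no dose effect — is surfaced through `converged` and `status`, never as
#' fabricated parameters.
#'
#' @param data Data frame with one row per measured well.
#' @param concentration Column of concentrations in micromolar (default
#'   `concentration_uM`).
#' @param response Column of normalized responses in percent of control
#'   (default `response_pct`).
#' @param top Fixed top plateau in percent (default 100).
#' @return A `dr_fit` with elements `pIC50`, `pIC50_se`, `pIC50_ci`,
#'   `bottom`, `bottom_se`, `bottom_ci`, `hill`, `hill_se`, `top`,
#'   `IC50_uM`, `rss`, `df_residual`, `n_obs`, `converged`, `status`,
#'   `data`.
#' @export
fit_4pl <- function(data, concentration = concentration_uM,
                    response = response_pct, top = 100) {
  conc <- dplyr::pull(data, {{ concentration }})
  resp <- dplyr::pull(data, {{ response }})
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative.", call. = FALSE)
  }
  keep <- is.finite(conc) & is.finite(resp) & conc > 0
  lc <- log10(conc[keep])
  y <- resp[keep]
  if (length(unique(lc)) < 4L) {
    stop("at least 4 distinct positive concentrations are required.", call. = FALSE)
  }
  df <- data.frame(lc = lc, y = y)

  out <- list(top = top, n_obs = nrow(df),
              data = tibble::tibble(log10_conc_uM = lc, response_pct = y))
  fail <- function(status) {
    out$converged <- FALSE
    out$status <- status
    out[c("pIC50", "pIC50_se", "bottom", "bottom_se", "hill", "hill_se",
          "IC50_uM", "rss")] <- NA_real_
    out$pIC50_ci <- c(NA_real_, NA_real_)
    out$bottom_ci <- c(NA_real_, NA_real_)
    structure(out, class = "dr_fit")
  }
  if (diff(range(y)) < 1e-8) {
    return(fail("no dose effect: responses are constant across concentrations"))
  }
  bottom0 <- max(min(y), 0)
  l50_0 <- stats::weighted.mean(lc, w = pmax(1e-6, (top - y) * (y - bottom0)))
  if (!is.finite(l50_0)) l50_0 <- stats::median(lc)
  # multi-start over plausible Hill slopes with box bounds: the 4PL surface
  # has flat valleys when plateaus are barely sampled, and a single start
  # can stall there
  lower <- c(bottom = -100, hill = 0.05, l50 = min(lc) - 3)
  upper <- c(bottom = top, hill = 20, l50 = max(lc) + 3)
  fit <- NULL
  last_err <- "fit did not converge"
  for (hill0 in c(1, 0.5, 2, 4)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - l50))),
        data = df,
        start = list(bottom = min(max(bottom0, lower[["bottom"]]), top - 1),
                     hill = hill0, l50 = l50_0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(cand, "error")) {
      last_err <- conditionMessage(cand)
    } else if (is.null(fit) || sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)) {
      fit <- cand
    }
  }
  if (is.null(fit)) return(fail(last_err))
  if (any(abs(stats::coef(fit) - lower) < 1e-8) ||
      any(abs(stats::coef(fit) - upper) < 1e-8)) {
    return(fail("fit stuck at a parameter bound; dose-response poorly determined by the data"))
  }
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc)))) {
    return(fail("fit covariance is not available; parameters ill-determined"))
  }
  se <- sqrt(diag(vc))
  # concentrations are in micromolar; pIC50 is on the molar scale
  out$pIC50 <- 6 - est[["l50"]]
  out$pIC50_se <- se[["l50"]]
  out$pIC50_ci <- out$pIC50 + c(-1, 1) * 1.96 * out$pIC50_se
  out$bottom <- est[["bottom"]]
  out$bottom_se <- se[["bottom"]]
  out$bottom_ci <- out$bottom + c(-1, 1) * 1.96 * out$bottom_se
  out$hill <- est[["hill"]]
  out$hill_se <- se[["hill"]]
  out$IC50_uM <- pIC50_to_IC50(out$pIC50)
  out$rss <- sum(stats::resid(fit)^2)
  out$df_residual <- stats::df.residual(fit)
  out$converged <- TRUE
  out$status <- "converged"
  out$fit <- fit
  structure(out, class = "dr_fit")
}

#' Convert pIC50 to IC50 in micromolar
#'
#' pIC50 is the negative base-10 logarithm of the molar half-maximal
#' inhibitory concentration, so IC50 in micromolar is `10^(-pIC50) * 1e6`.
#'
#' @param pIC50 Numeric pIC50 value(s).
#' @return IC50 in micromolar.
#' @export
pIC50_to_IC50 <- function(pIC50) 10^(-pIC50) * 1e6

#' Compare two fitted pIC50 values
#'
#' Two-sided z-test on the difference of the fitted pIC50 values using the
#' standard errors of the two fits: `z = (a - b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param fit_a,fit_b Converged `dr_fit` objects.
#' @return A one-row tibble with `difference` (a minus b), `z`, `p_value`.
#' @export
compare_pIC50 <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "dr_fit"), inherits(fit_b, "dr_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both fits must have converged.", call. = FALSE)
  }
  d <- fit_a$pIC50 - fit_b$pIC50
  se <- sqrt(fit_a$pIC50_se^2 + fit_b$pIC50_se^2)
  z <- if (se > 0) d / se else ifelse(d == 0, 0, sign(d) * Inf)
  tibble::tibble(difference = d, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.dr_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "<dr_fit> pIC50 %.2f [%.2f, %.2f]  IC50 %.3g uM  bottom %.1f%% [%.1f, %.1f]  hill %.2f  (n = %d)\n",
      x$pIC50, x$pIC50_ci[1], x$pIC50_ci[2], x$IC50_uM,
      x$bottom, x$bottom_ci[1], x$bottom_ci[2], x$hill, x$n_obs))
  } else {
    cat(sprintf("<dr_fit> not converged: %s\n", x$status))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dose-response fit
#'
#' @param x A `dr_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`pIC50`, `bottom`, `hill`):
#'   `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pIC50", "bottom", "hill"),
    estimate = c(x$pIC50, x$bottom, x$hill),
    std.error = c(x$pIC50_se, x$bottom_se, x$hill_se),
    conf.low = c(x$pIC50_ci[1], x$bottom_ci[1],
                 x$hill - 1.96 * x$hill_se),
    conf.high = c(x$pIC50_ci[2], x$bottom_ci[2],
                  x$hill + 1.96 * x$hill_se))
}

#' One-row summary of a dose-response fit
#'
#' @param x A `dr_fit`.
#' @param ... Unused.
#' @return A one-row tibble mirroring a results-table row: pIC50 with CI,
#'   IC50 in micromolar, bottom plateau with CI, Hill slope, fit quality.
#' @export
glance.dr_fit <- function(x, ...) {
  tibble::tibble(
    pIC50 = x$pIC50, pIC50_lo = x$pIC50_ci[1], pIC50_hi = x$pIC50_ci[2],
    IC50_uM = x$IC50_uM,
    bottom_pct = x$bottom, bottom_lo = x$bottom_ci[1],
    bottom_hi = x$bottom_ci[2],
    hill = x$hill, top_pct = x$top,
    rss = x$rss, n_obs = x$n_obs, converged = x$converged)
}

#' Plot a dose-response fit
#'
#' Points are the normalized responses; the line is the fitted
#' four-parameter logistic curve on the log10 concentration axis.
#'
#' @param object A converged `dr_fit`.
#' @param n_curve Number of points used to draw the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dr_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_conc_uM,
                                       y = .data$response_pct)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 concentration (uM)", y = "% of control")
  if (isTRUE(object$converged)) {
    lc <- seq(min(d$log10_conc_uM), max(d$log10_conc_uM), length.out = n_curve)
    l50 <- 6 - object$pIC50
    curve <- tibble::tibble(
      log10_conc_uM = lc,
      response_pct = object$bottom + (object$top - object$bottom) /
        (1 + 10^(object$hill * (lc - l50))))
    p <- p + ggplot2::geom_line(data = curve, color = "#2166ac")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
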