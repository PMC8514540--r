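#' Multi-scale feature configuration
#'
#' Defines the scales and boundary handling of the per-pixel feature bank
#' used for nucleus/background pixel classification. Six filter families are
#' computed: Gaussian smoothing, Laplacian of Gaussian, Gaussian gradient
#' magnitude, difference of Gaussians, structure-tensor eigenvalues and
#' Hessian-of-Gaussian eigenvalues. Smoothing is evaluated at `sigma0` and at
#' every scale in `sigmas`; the five derivative families are evaluated at
#' `sigmas` only, giving 65 features under the defaults.
#'
#' @param sigma0 Finest smoothing scale in pixels (default 0.3).
#' @param sigmas Increasing vector of scales in pixels for all families
#'   (default `c(0.7, 1, 1.6, 3.5, 5, 10, 20, 35)`).
#' @param boundary_mode Image-border handling: `"reflect"` (default,
#'   half-sample symmetric), `"nearest"`, or `"constant"` (zero padding).
#' @param dog_inner_ratio Inner scale of the difference of Gaussians as a
#'   fraction of sigma: DoG(s) = G(s) - G(dog_inner_ratio * s).
#' @param st_outer_ratio Structure-tensor integration scale as a fraction of
#'   the gradient scale sigma.
#' @return A `feature_config` object.
#' @export
feature_config <- function(sigma0 = 0.3,
                           sigmas = c(0.7, 1, 1.6, 3.5, 5, 10, 20, 35),
                           boundary_mode = c("reflect", "nearest", "constant"),
                           dog_inner_ratio = 0.66,
                           st_outer_ratio = 0.5) {
  boundary_mode <- match.arg(boundary_mode)
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 <= 0) {
    stop("`sigma0` must be a single positive number.", call. = FALSE)
  }
  if (length(sigmas) < 1L || any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE)) {
    stop("`sigmas` must be strictly increasing and positive.", call. = FALSE)
  }
  cfg <- structure(
    list(sigma0 = sigma0, sigmas = as.numeric(sigmas),
         boundary_mode = boundary_mode,
         dog_inner_ratio = dog_inner_ratio, st_outer_ratio = st_outer_ratio),
    class = "feature_config")
  cfg$hash <- rlang::hash(unclass(cfg)[c("sigma0", "sigmas", "boundary_mode",
                                         "dog_inner_ratio", "st_outer_ratio")])
  cfg
}

# sampled Gaussian (derivative) kernel, calibrated on the grid so that
# order 0 sums to 1, order 1 responds to a unit ramp with exactly 1, and
# order 2 responds to x^2/2 with exactly 1 (and kills constants exactly)
gauss_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    return(k / (-sum(x * k)))
  }
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k <- k - mean(k)
  k / (sum(x^2 * k) / 2)
}

# fold an out-of-range 0-based index back into [0, n-1]
fold_index <- function(i, n, mode) {
  if (mode == "nearest") return(pmin(pmax(i, 0L), n - 1L))
  if (mode == "constant") return(ifelse(i < 0L | i >= n, NA_integer_, i))
  m <- ((i %% (2L * n)) + 2L * n) %% (2L * n)
  ifelse(m < n, m, 2L * n - 1L - m)
}

.op_cache <- new.env(parent = emptyenv())

# n x n dense operator applying the 1-D kernel with boundary handling;
# out = O %*% f gives the convolution of f with the kernel
gauss_operator <- function(n, sigma, order, mode) {
  key <- sprintf("%d|%.12g|%d|%s", n, sigma, order, mode)
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gauss_kernel(sigma, order)
  r <- (length(k) - 1L) %/% 2L
  O <- matrix(0, n, n)
  i0 <- 0:(n - 1L)
  for (j in seq(-r, r)) {
    src <- fold_index(i0 - j, n, mode)
    ok <- !is.na(src)
    if (any(ok)) {
      idx <- cbind(i0[ok] + 1L, src[ok] + 1L)
      O[idx] <- O[idx] + k[j + r + 1L]
    }
  }
  .op_cache[[key]] <- O
  O
}

# separable Gaussian-derivative filter: order_row along rows (y),
# order_col along columns (x)
gauss_filter <- function(image, sigma, order_row = 0L, order_col = 0L,
                         mode = "reflect") {
  Orow <- gauss_operator(nrow(image), sigma, order_row, mode)
  Ocol <- gauss_operator(ncol(image), sigma, order_col, mode)
  Orow %*% image %*% t(Ocol)
}

#' Gaussian smoothing of an image
#'
#' Linear, shift-equivariant smoothing by a sampled Gaussian kernel applied
#' separably. Under the default reflect boundary the image mean is preserved.
#'
#' @param image Numeric matrix (one image channel).
#' @param sigma Smoothing scale in pixels; must be positive.
#' @param mode Boundary handling, as in [feature_config()].
#' @return A numeric matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma, mode = "reflect") {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  stopifnot(is.matrix(image))
  gauss_filter(image, sigma, 0L, 0L, mode)
}

# eigenvalues of the symmetric 2x2 field [[a, b], [b, c]], elementwise;
# returns list(hi, lo) with hi >= lo
sym_eigen2 <- function(a, b, c) {
  tr2 <- (a + c) / 2
  disc <- sqrt(((a - c) / 2)^2 + b^2)
  list(hi = tr2 + disc, lo = tr2 - disc)
}

#' Compute the multi-scale pixel feature stack
#'
#' Evaluates the six filter families of the pixel-classification feature bank
#' on one image channel: Gaussian smoothing at `sigma0` and each sigma,
#' then at each sigma the Laplacian of Gaussian (trace of the Gaussian
#' Hessian), the Gaussian gradient magnitude, the difference of Gaussians,
#' the two structure-tensor eigenvalues (gradient scale sigma, integration
#' scale `st_outer_ratio * sigma`) and the two Hessian eigenvalues (ordered
#' descending). 65 features under the default configuration.
#'
#' @param image Numeric matrix of raw pixel intensities (no normalization is
#'   applied).
#' @param config A [feature_config()].
#' @return A `feature_stack`: list with `values` (rows x cols x n_features
#'   array), `names` (feature identifiers), `dim`, and `config`.
#' @export
compute_features <- function(image, config = feature_config()) {
  stopifnot(is.matrix(image), inherits(config, "feature_config"))
  n_bad <- sum(!is.finite(image))
  if (n_bad > 0L) {
    stop(sprintf("`image` contains %d non-finite pixel(s).", n_bad), call. = FALSE)
  }
  mode <- config$boundary_mode
  sig <- config$sigmas
  planes <- list()
  nm <- character(0)
  add <- function(p, name) {
    planes[[length(planes) + 1L]] <<- p
    nm[length(nm) + 1L] <<- name
  }
  sname <- function(s) format(s, trim = TRUE, drop0trailing = TRUE)

  add(gauss_filter(image, config$sigma0, 0L, 0L, mode),
      paste0("gauss_s", sname(config$sigma0)))
  smooth <- lapply(sig, function(s) gauss_filter(image, s, 0L, 0L, mode))
  for (i in seq_along(sig)) add(smooth[[i]], paste0("gauss_s", sname(sig[i])))

  hess <- vector("list", length(sig))
  grad <- vector("list", length(sig))
  for (i in seq_along(sig)) {
    s <- sig[i]
    gyy <- gauss_filter(image, s, 2L, 0L, mode)
    gxx <- gauss_filter(image, s, 0L, 2L, mode)
    gxy <- gauss_filter(image, s, 1L, 1L, mode)
    gy <- gauss_filter(image, s, 1L, 0L, mode)
    gx <- gauss_filter(image, s, 0L, 1L, mode)
    hess[[i]] <- list(xx = gxx, yy = gyy, xy = gxy)
    grad[[i]] <- list(x = gx, y = gy)
  }
  for (i in seq_along(sig)) {
    add(hess[[i]]$xx + hess[[i]]$yy, paste0("log_s", sname(sig[i])))
  }
  for (i in seq_along(sig)) {
    add(sqrt(grad[[i]]$x^2 + grad[[i]]$y^2), paste0("gradmag_s", sname(sig[i])))
  }
  for (i in seq_along(sig)) {
    s <- sig[i]
    inner <- gauss_filter(image, config$dog_inner_ratio * s, 0L, 0L, mode)
    add(smooth[[i]] - inner, paste0("dog_s", sname(s)))
  }
  for (i in seq_along(sig)) {
    s <- sig[i]
    so <- config$st_outer_ratio * s
    gx <- grad[[i]]$x; gy <- grad[[i]]$y
    j11 <- gauss_filter(gx * gx, so, 0L, 0L, mode)
    j22 <- gauss_filter(gy * gy, so, 0L, 0L, mode)
    j12 <- gauss_filter(gx * gy, so, 0L, 0L, mode)
    ev <- sym_eigen2(j11, j12, j22)
    add(pmax(ev$hi, 0), paste0("steig1_s", sname(s)))
    add(pmax(ev$lo, 0), paste0("steig2_s", sname(s)))
  }
  for (i in seq_along(sig)) {
    ev <- sym_eigen2(hess[[i]]$xx, hess[[i]]$xy, hess[[i]]$yy)
    add(ev$hi, paste0("hesseig1_s", sname(sig[i])))
    add(ev$lo, paste0("hesseig2_s", sname(sig[i])))
  }

  values <- array(unlist(planes, use.names = FALSE),
                  dim = c(nrow(image), ncol(image), length(planes)))
  structure(list(values = values, names = nm,
                 dim = dim(image), config = config),
            class = "feature_stack")
}

#' Flatten a feature stack to a pixels-by-features matrix
#'
#' @param stack A `feature_stack` from [compute_features()].
#' @return Numeric matrix with one row per pixel (column-major pixel order)
#'   and one named column per feature.
#' @export
feature_matrix <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  m <- matrix(stack$values, nrow = prod(stack$dim),
              ncol = length(stack$names))
  colnames(m) <- stack$names
  m
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d x %d pixels, %d features\n",
              x$dim[1], x$dim[2], length(x$names)))
  invisible(x)
}
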