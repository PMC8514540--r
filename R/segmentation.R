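#' Binarize a probability map
#'
#' A pixel is foreground iff its nucleus probability is greater than or
#' equal to the threshold (a probability exactly at the threshold counts as
#' nucleus).
#'
#' @param pmap Numeric matrix of nucleus probabilities in [0, 1].
#' @param threshold Probability cutoff, strictly between 0 and 1
#'   (default 0.5).
#' @return Logical matrix of the same shape.
#' @export
binarize <- function(pmap, threshold = 0.5) {
  stopifnot(is.matrix(pmap))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (any(pmap < 0 | pmap > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1].", call. = FALSE)
  }
  pmap >= threshold
}

#' Label connected components of a binary mask
#'
#' Groups foreground pixels into objects under 4- or 8-adjacency. Labels are
#' assigned 1..K in order of each component's first pixel in column-major
#' scan order, so labeling is deterministic.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of labels (0 = background) with attributes
#'   `connectivity` and `n_objects`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8.", call. = FALSE)
  }
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) {
    attr(out, "connectivity") <- connectivity
    attr(out, "n_objects") <- 0L
    return(out)
  }
  vid <- integer(nr * nc)
  vid[fg] <- seq_along(fg)
  row_i <- ((fg - 1L) %% nr) + 1L
  col_i <- ((fg - 1L) %/% nr) + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (s in shifts) {
    r2 <- row_i + s[1L]; c2 <- col_i + s[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vid[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(vid[fg[ok]][hit], vid[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel by first occurrence in column-major order (fg is already sorted)
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  out[fg] <- relab[comp]
  attr(out, "connectivity") <- connectivity
  attr(out, "n_objects") <- length(first)
  out
}

#' Remove small objects from a label map
#'
#' Deletes components whose pixel area is strictly smaller than
#' `min_area_px` — objects below the cutoff are treated as imaging or
#' fixation artifacts. Survivors are relabeled 1..K preserving their
#' original label order; the operation is idempotent.
#'
#' @param labels Integer label matrix (0 = background).
#' @param min_area_px Minimum area in pixels to keep (default 200).
#' @return Filtered and relabeled integer label matrix.
#' @export
filter_small <- function(labels, min_area_px = 200L) {
  stopifnot(is.matrix(labels))
  if (!is.numeric(min_area_px) || length(min_area_px) != 1L || min_area_px < 0) {
    stop("`min_area_px` must be a single non-negative number.", call. = FALSE)
  }
  k <- max(labels, 0L)
  out <- matrix(0L, nrow(labels), ncol(labels))
  conn <- attr(labels, "connectivity")
  if (k == 0L) {
    attr(out, "connectivity") <- conn
    attr(out, "n_objects") <- 0L
    return(out)
  }
  areas <- tabulate(labels[labels > 0L], nbins = k)
  keep <- which(areas >= min_area_px)
  relab <- integer(k)
  relab[keep] <- seq_along(keep)
  pos <- labels > 0L
  out[pos] <- relab[labels[pos]]
  attr(out, "connectivity") <- conn
  attr(out, "n_objects") <- length(keep)
  out
}

#' Convert a pixel area to square micrometres
#'
#' @param area_px Area in pixels.
#' @param pixel_pitch Pixel side length in micrometres per pixel (default
#'   0.3225, at which 200 px corresponds to 20.8 square micrometres).
#' @return Area in square micrometres: `area_px * pixel_pitch^2`.
#' @export
area_to_um2 <- function(area_px, pixel_pitch = 0.3225) {
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0) {
    stop("`pixel_pitch` must be a single positive number.", call. = FALSE)
  }
  area_px * pixel_pitch^2
}

#' Per-nucleus intensity measurements in both channels
#'
#' For each labeled nucleus computes the area, centroid, and the mean and
#' total raw intensity over exactly the labeled pixels in the DAPI and
#' gamma-H2AX channels. No background subtraction or normalization is
#' applied; intensities are reported in native camera units.
#'
#' @param labels Integer label matrix (filtered, 0 = background).
#' @param dapi,gh2ax Numeric matrices of raw intensities, same shape as
#'   `labels`.
#' @param pixel_pitch Micrometres per pixel side (default 0.3225).
#' @return A tibble with one row per nucleus: `label`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `mean_dapi`, `total_dapi`,
#'   `mean_gh2ax`, `total_gh2ax`.
#' @export
measure_nuclei <- function(labels, dapi, gh2ax, pixel_pitch = 0.3225) {
  stopifnot(is.matrix(labels), is.matrix(dapi), is.matrix(gh2ax))
  if (!identical(dim(labels), dim(dapi)) || !identical(dim(labels), dim(gh2ax))) {
    stop("`labels`, `dapi` and `gh2ax` must share the same shape.", call. = FALSE)
  }
  k <- max(labels, 0L)
  if (k == 0L) {
    return(tibble::tibble(
      label = integer(0), area_px = integer(0), area_um2 = numeric(0),
      centroid_row = numeric(0), centroid_col = numeric(0),
      mean_dapi = numeric(0), total_dapi = numeric(0),
      mean_gh2ax = numeric(0), total_gh2ax = numeric(0)))
  }
  pos <- which(labels > 0L)
  lab <- labels[pos]
  nr <- nrow(labels)
  rows <- ((pos - 1L) %% nr) + 1L
  cols <- ((pos - 1L) %/% nr) + 1L
  area <- tabulate(lab, nbins = k)
  if (any(area == 0L)) {
    stop("label map has gaps; relabel (e.g. via filter_small) before measuring.",
         call. = FALSE)
  }
  sum_by <- function(v) as.numeric(rowsum(v, lab, reorder = TRUE))
  tot_d <- sum_by(dapi[pos])
  tot_g <- sum_by(gh2ax[pos])
  tibble::tibble(
    label = seq_len(k),
    area_px = as.integer(area),
    area_um2 = area_to_um2(area, pixel_pitch),
    centroid_row = sum_by(as.numeric(rows)) / area,
    centroid_col = sum_by(as.numeric(cols)) / area,
    mean_dapi = tot_d / area,
    total_dapi = tot_d,
    mean_gh2ax = tot_g / area,
    total_gh2ax = tot_g)
}
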