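#' Build an annotation mask
#'
#' Encodes sparse or dense pixel annotations for classifier training:
#' 0 = unlabeled, 1 = nucleus, 2 = background.
#'
#' @param labels Integer matrix with values in {0, 1, 2}.
#' @return An integer matrix of class `annotation_mask`.
#' @export
annotation_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  if (!all(labels %in% 0:2)) {
    stop("annotation values must be 0 (unlabeled), 1 (nucleus) or 2 (background).",
         call. = FALSE)
  }
  structure(matrix(as.integer(labels), nrow(labels)), class = "annotation_mask")
}

#' Dense annotations from a ground-truth label map
#'
#' Every labeled pixel becomes a nucleus annotation and every other pixel a
#' background annotation — the scripted equivalent of fully annotating a
#' training field.
#'
#' @param labels Integer label matrix (0 = background).
#' @return An `annotation_mask`.
#' @export
labels_to_annotations <- function(labels) {
  annotation_mask(ifelse(labels > 0L, 1L, 2L))
}

#' Train the nucleus/background pixel classifier
#'
#' Fits a probability random forest on the labeled pixels of one or more
#' feature stacks. Only labeled pixels enter training; classes are used
#' as-is with no reweighting, mirroring a sparse-annotation workflow. When a
#' class has more than `max_pixels_per_class` labeled pixels a deterministic
#' subsample (driven by `seed`) is used, which keeps training fast on densely
#' annotated fields without changing the learned decision surface
#' appreciably.
#'
#' @param stacks List of `feature_stack` objects (or a single one).
#' @param annotations List of `annotation_mask` objects aligned with
#'   `stacks`.
#' @param n_trees Number of trees in the forest (default 100).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param max_pixels_per_class Cap on training pixels per class (default
#'   10000; `Inf` to use all labeled pixels).
#' @return A `pixel_classifier` with the fitted forest, the ordered feature
#'   names, the feature-config hash and training metadata.
#' @export
train_pixel_classifier <- function(stacks, annotations, n_trees = 100L,
                                   seed, max_pixels_per_class = 10000L) {
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  if (inherits(annotations, "annotation_mask")) annotations <- list(annotations)
  stopifnot(length(stacks) == length(annotations), length(stacks) >= 1L)
  if (missing(seed)) stop("`seed` is required; no hidden global state.", call. = FALSE)

  ref_names <- stacks[[1L]]$names
  ref_hash <- stacks[[1L]]$config$hash
  xs <- vector("list", length(stacks))
  ys <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    if (!identical(st$names, ref_names)) {
      stop(sprintf("feature names of stack %d do not match stack 1.", i),
           call. = FALSE)
    }
    ann <- annotations[[i]]
    stopifnot(inherits(ann, "annotation_mask"),
              identical(dim(unclass(ann)), st$dim))
    lab <- as.integer(ann)
    keep <- which(lab != 0L)
    xs[[i]] <- feature_matrix(st)[keep, , drop = FALSE]
    ys[[i]] <- lab[keep]
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  cls_codes <- c(nucleus = 1L, background = 2L)
  for (k in names(cls_codes)) {
    if (!any(y == cls_codes[[k]])) {
      stop(sprintf("no labeled '%s' pixels in the annotations.", k), call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    sel <- unlist(lapply(c(1L, 2L), function(cls) {
      idx <- which(y == cls)
      if (length(idx) > max_pixels_per_class) {
        sort(sample(idx, max_pixels_per_class))
      } else idx
    }))
    x <- x[sel, , drop = FALSE]
    y <- y[sel]
    fit <- ranger::ranger(
      x = x, y = factor(y, levels = c(1L, 2L), labels = c("nucleus", "background")),
      num.trees = n_trees, probability = TRUE,
      seed = seed, num.threads = 1L)
  })
  structure(
    list(forest = fit, feature_names = ref_names, config_hash = ref_hash,
         training_meta = list(n_trees = as.integer(n_trees), seed = seed,
                              n_training_pixels = length(y)),
         version = 1L),
    class = "pixel_classifier")
}

#' Per-pixel nucleus probability map
#'
#' Applies a trained pixel classifier to a feature stack. The stack must
#' carry the same feature names, in the same order, and the same
#' feature-config hash as the stack(s) the model was trained on; a mismatch
#' aborts rather than silently predicting from misaligned features.
#'
#' @param model A `pixel_classifier`.
#' @param stack A `feature_stack` for the field to classify.
#' @return Numeric matrix of nucleus probabilities in [0, 1] with the field's
#'   shape. The background probability is its complement.
#' @export
predict_nucleus_prob <- function(model, stack) {
  stopifnot(inherits(model, "pixel_classifier"), inherits(stack, "feature_stack"))
  if (!identical(model$feature_names, stack$names)) {
    missing_f <- setdiff(model$feature_names, stack$names)
    extra_f <- setdiff(stack$names, model$feature_names)
    stop(sprintf(
      "feature mismatch between model and stack: missing [%s]; extra [%s].",
      paste(missing_f, collapse = ", "), paste(extra_f, collapse = ", ")),
      call. = FALSE)
  }
  if (!identical(model$config_hash, stack$config$hash)) {
    stop("feature-config hash mismatch: the stack was computed with a different configuration than the model was trained on.",
         call. = FALSE)
  }
  pr <- stats::predict(model$forest, data = feature_matrix(stack),
                       num.threads = 1L)$predictions
  matrix(pr[, "nucleus"], nrow = stack$dim[1], ncol = stack$dim[2])
}

#' Save / load a pixel classifier
#'
#' Serializes the model to a single self-describing file embedding the
#' feature names, the feature-config hash and a format version.
#'
#' @param model A `pixel_classifier`.
#' @param path File path.
#' @return `save_pixel_classifier` returns `path` invisibly;
#'   `load_pixel_classifier` returns the model.
#' @export
save_pixel_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pixel_classifier") || is.null(model$version)) {
    stop("file does not contain a pixel_classifier model.", call. = FALSE)
  }
  model
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d trees, %d features, %d training pixels (seed %s)\n",
              x$training_meta$n_trees, length(x$feature_names),
              x$training_meta$n_training_pixels,
              format(x$training_meta$seed)))
  invisible(x)
}
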