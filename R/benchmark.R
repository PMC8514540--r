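#' Seeded segmentation benchmark with held-out fields
#'
#' Generates a set of synthetic fields with exact ground truth, trains the
#' pixel classifier on the first `n_train` fields' full ground-truth
#' annotations, runs the segmentation chain (probability threshold,
#' connected components, size filter) on the held-out fields, and scores the
#' result at object level (greedy IoU matching) and pixel level (MCC of the
#' post-filter foreground mask). This is the package's standing quality
#' check for the whole train-predict-segment path.
#'
#' @param seed Seed for the scene generator; per-field seeds are derived
#'   from it.
#' @param train_seed Seed for classifier training.
#' @param n_fields Total number of fields (default 12).
#' @param n_train Number of training fields (default 4; the rest are held
#'   out).
#' @param params A [scene_params()] template (its seed is overridden per
#'   field).
#' @param config A [pipeline_config()].
#' @param n_trees Trees in the random forest (default 100).
#' @param iou_threshold Object-matching IoU threshold (default 0.5).
#' @param max_pixels_per_class Training-pixel cap per class (default 8000).
#' @return A list with `metrics` (one-row tibble: precision, recall, f1,
#'   mcc, counts), `per_field` (per-held-out-field tibble), `model`, and
#'   `n_gt_objects` (ground-truth nuclei in the held-out fields).
#' @export
segmentation_benchmark <- function(seed = 42L, train_seed = 0L,
                                   n_fields = 12L, n_train = 4L,
                                   params = scene_params(),
                                   config = pipeline_config(),
                                   n_trees = 100L, iou_threshold = 0.5,
                                   max_pixels_per_class = 8000L) {
  stopifnot(n_train >= 1L, n_fields > n_train)
  scenes <- lapply(seq_len(n_fields), function(i) {
    generate_scene(scene_params_with(params, seed = derive_seed(seed, i, 0L)))
  })
  train_idx <- seq_len(n_train)
  stacks <- lapply(scenes[train_idx],
                   function(s) compute_features(s$dapi, config$features))
  anns <- lapply(scenes[train_idx],
                 function(s) labels_to_annotations(s$true_labels))
  model <- train_pixel_classifier(stacks, anns, n_trees = n_trees,
                                  seed = train_seed,
                                  max_pixels_per_class = max_pixels_per_class)

  test_idx <- setdiff(seq_len(n_fields), train_idx)
  tp <- 0L; fp <- 0L; fn <- 0L
  px_tp <- 0; px_tn <- 0; px_fp <- 0; px_fn <- 0
  per_field <- vector("list", length(test_idx))
  for (j in seq_along(test_idx)) {
    s <- scenes[[test_idx[j]]]
    rec <- run_field(s$dapi, s$gh2ax, model, config)
    pred <- attr(rec, "labels")
    m <- match_objects(s$true_labels, pred, iou_threshold)
    tp <- tp + m$n_tp; fp <- fp + m$n_fp; fn <- fn + m$n_fn
    g <- s$true_labels > 0L; p <- pred > 0L
    px_tp <- px_tp + sum(g & p); px_tn <- px_tn + sum(!g & !p)
    px_fp <- px_fp + sum(!g & p); px_fn <- px_fn + sum(g & !p)
    per_field[[j]] <- tibble::tibble(
      field = test_idx[j], n_gt = m$n_gt, n_pred = m$n_pred,
      n_tp = m$n_tp, n_fp = m$n_fp, n_fn = m$n_fn,
      mean_iou = if (nrow(m$pairs) > 0) mean(m$pairs$iou) else NA_real_)
  }
  om <- object_metrics(tp, fp, fn)
  metrics <- dplyr::mutate(om, mcc = mcc_from_counts(px_tp, px_tn, px_fp, px_fn))
  list(metrics = metrics,
       per_field = dplyr::bind_rows(per_field),
       model = model,
       n_gt_objects = tp + fn)
}
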