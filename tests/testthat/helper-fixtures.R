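# Shared small fixtures, built once per session and memoized: a compact
# scene geometry and a classifier trained on it, reused by classifier and
# pipeline tests to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

small_scene_params <- function(seed, n_nuclei = 5L) {
  scene_params(field_shape = c(128L, 128L), n_nuclei = n_nuclei, seed = seed)
}

get_test_config <- function() pipeline_config()

# classifier trained on two small fields' full ground truth
get_test_model <- function() {
  if (is.null(.fixture_cache$model)) {
    cfg <- get_test_config()
    scenes <- lapply(c(201L, 202L), function(s) {
      generate_scene(small_scene_params(s))
    })
    stacks <- lapply(scenes, function(s) compute_features(s$dapi, cfg$features))
    anns <- lapply(scenes, function(s) labels_to_annotations(s$true_labels))
    .fixture_cache$model <- train_pixel_classifier(
      stacks, anns, n_trees = 50L, seed = 11L, max_pixels_per_class = 3000L)
  }
  .fixture_cache$model
}
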