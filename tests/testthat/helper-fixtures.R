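# shared fixtures: small cohorts and fast training configs used across
# the unit tests (acceptance tests run at study scale in their own file)

quick_fusion <- function(seed = 1L, max_epochs = 40L, ...) {
  fusion_config(max_epochs = max_epochs, patience = max_epochs,
                seed = seed, ...)
}

quick_mlp <- function(seed = 1L, max_epochs = 40L, ...) {
  mlp_config(max_epochs = max_epochs, patience = max_epochs,
             seed = seed, ...)
}

small_cohort <- function(n = 150L, effect = c(0, 0, 0, 2.5, 0), seed = 4L,
                         n_features = 400L, ...) {
  generate_feature_cohort(feature_cohort_config(
    n_subjects = n, effect_size = effect, n_features = n_features,
    informative_fraction = 1 / n_features, seed = seed, ...))
}

# tiny all-zero clip in the video_clip layout
zero_clip <- function(modality = "t1") {
  structure(list(frames = array(0L, dim = c(150L, 128L, 128L)),
                 source_modality = modality),
            class = "video_clip")
}

random_clip <- function(seed = 1L, modality = "t1") {
  withr::with_seed(seed, {
    structure(list(frames = array(sample(0:255, 150L * 128L * 128L,
                                         replace = TRUE),
                                  dim = c(150L, 128L, 128L)),
                   source_modality = modality),
              class = "video_clip")
  })
}

# small phantom whose standardized form is the full 240 x 240 x 150 grid
small_phantom_config <- function(seed = 1L) {
  phantom_config(grid_shape = c(120L, 120L, 75L), spacing_mm = c(2, 2, 2),
                 tumor_center = c(60, 60, 37), tumor_radii = c(15, 12, 8),
                 noise_sd = 2, seed = seed)
}
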