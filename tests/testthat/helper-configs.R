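# Small configurations used across the unit tests: coarse detector grids and
# short filter windows keep a full pipeline run in seconds while preserving
# every structural property (two segments, overlap, crop, interior filtering).

tiny_grids <- function() {
  default_grids(by_a = 0.006, by_b = 0.0128)
}

tiny_cohort_config <- function(seed = 42L, contamination = 0.1, ...) {
  cohort_config(n_experimental = 4L, n_control = 2L,
                legs = "left", sites = c("proximal", "distal"),
                n_locations = 3L, in_vitro_repeats = 3L,
                in_vivo_repeats = 4L,
                contamination_rate = contamination,
                seed = seed, grids = tiny_grids(), ...)
}

tiny_preprocess_config <- function() {
  preprocess_config(window_a = 21L, window_b = 15L)
}

tiny_pipeline_config <- function(seed = 42L, contamination = 0.1,
                                 targets = c("thickness", "pg_full"),
                                 out_dir = NULL) {
  pipeline_config(
    cohort = tiny_cohort_config(seed = seed, contamination = contamination),
    preprocessing = tiny_preprocess_config(),
    training = train_config(max_epochs = c(conv = 2L, dense = 5L)),
    targets = targets,
    out_dir = out_dir)
}
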