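# Shared fixtures, all generated in code.

# Small scene that renders fast; geometry scaled down from the default.
small_scene <- function(stress_fraction = 0, seed = 1, scale = 1, ...) {
  scene_config(height = 96, width = 96, n_leaves = 6,
               leaf_length_range = c(18, 26), stress_fraction = stress_fraction,
               seed = seed, scale = scale, ...)
}

# Labelled pixel table drawn from the default separable populations.
gaussian_ground_truth <- function(n_per_class = 500, seed = 1) {
  pops <- default_populations()
  ns <- sample_pixels(pops$non_stressed, n_per_class, seed = seed)
  st <- sample_pixels(pops$stressed, n_per_class, seed = seed + 1)
  tibble::tibble(
    r = c(ns[, 1], st[, 1]), g = c(ns[, 2], st[, 2]), b = c(ns[, 3], st[, 3]),
    label = rep(c("non_stressed", "stressed"), each = n_per_class)
  )
}

# Two point-mass classes: every family separates them perfectly.
point_mass_ground_truth <- function(n_per_class = 100) {
  tibble::tibble(
    r = rep(c(10, 200), each = n_per_class),
    g = rep(c(200, 150), each = n_per_class),
    b = rep(c(30, 20), each = n_per_class),
    label = rep(c("non_stressed", "stressed"), each = n_per_class)
  )
}

# A tiny simulated experiment shared by pipeline tests; built once per run.
tiny_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "afpheno-tiny-experiment")
      cfg <- default_pipeline_config()
      cfg$seed <- 42
      cfg$simulation$replicates <- 2
      cfg$simulation$days <- seq(8, 24, by = 4)
      ds <- simulate_dataset(cfg, dir)
      cache <<- list(config = cfg, dataset = ds, root = dir)
    }
    cache
  }
})

# Full pipeline over the tiny experiment, run once and shared.
tiny_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      exp <- tiny_experiment()
      cache <<- suppressWarnings(run_pipeline(
        exp$dataset$manifest, root = exp$root, config = exp$config,
        out_dir = file.path(exp$root, "out-shared"), truth = exp$dataset$truth))
    }
    cache
  }
})

# Rows that carry real phenotype values (segmentation succeeded).
drop_na_pheno <- function(p) p[!p$segmentation_empty, ]
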