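# End-to-end pipeline: simulate (or load) a dataset, segment, build ground
# truth, train and select the classifier, classify every image, compute
# phenotypes and genotype comparisons. Staged execution and the end-to-end
# runner share these functions, so chained stages reproduce `run_pipeline()`
# byte for byte given the same seeds.

#' Default pipeline configuration
#'
#' Nested named list with one section per stage plus a global seed. Stage
#' seeds are derived from the global seed so every stage is independently
#' reproducible.
#'
#' @return A named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    simulation = list(
      replicates = 6, days = 5:30, onset_day = 10,
      image_height = 160, image_width = 160, n_leaves = 8, noise_sd = 4,
      scale_range = c(0.35, 1)
    ),
    segmentation = list(
      mode = "auto", hue_range = c(-40, 80), saturation_range = c(0.30, 1),
      value_range = c(0.35, 1), red_threshold = 110, red_margin = 20,
      min_component_area = 15, morphology_radius = 1, auto_switch_area = 1500
    ),
    ground_truth = list(n_annotation_images = 3, n_per_class = 4, patch_radius = 4),
    classifier = list(fractions = c(0.6, 0.2, 0.2)),
    phenotypes = list(window = 3)
  )
}

# Recursively reject keys that the default config does not know about.
check_config_keys <- function(cfg, ref, path = "config") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0) {
    stop_afpheno(paste0("unknown ", path, " key(s): ", paste(unknown, collapse = ", ")),
                 "config_error")
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      check_config_keys(as.list(cfg[[k]]), ref[[k]], paste0(path, "$", k))
    }
  }
  invisible(TRUE)
}

#' Load a pipeline configuration from JSON
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path JSON file, or `NULL` for the defaults.
#' @return A config list (see [default_pipeline_config()]).
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_afpheno(paste0("config not found: ", path), "not_found_error")
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_config_keys(user, cfg)
  modify <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(upd[[k]])) {
        modify(base[[k]], upd[[k]])
      } else {
        upd[[k]]
      }
    }
    base
  }
  modify(cfg, user)
}

seg_config_from <- function(config) {
  s <- config$segmentation
  segmentation_config(mode = s$mode, hue_range = s$hue_range,
                      saturation_range = s$saturation_range,
                      value_range = s$value_range, red_threshold = s$red_threshold,
                      red_margin = s$red_margin,
                      min_component_area = s$min_component_area,
                      morphology_radius = s$morphology_radius,
                      auto_switch_area = s$auto_switch_area)
}

#' Simulate a dataset under a pipeline configuration
#'
#' Thin wrapper over [simulate_drought_experiment()] with the default
#' three-genotype drought curves.
#'
#' @param config Pipeline config (see [default_pipeline_config()]).
#' @param out_dir Dataset directory to create.
#' @param curves Optional list of [drought_curve()] objects; defaults to
#'   [default_genotype_curves()] at the configured onset day.
#' @return See [simulate_drought_experiment()].
#' @export
simulate_dataset <- function(config = default_pipeline_config(), out_dir,
                             curves = NULL) {
  sim <- config$simulation
  curves <- curves %||% default_genotype_curves(onset_day = sim$onset_day)
  base_scene <- scene_config(height = sim$image_height, width = sim$image_width,
                             n_leaves = sim$n_leaves, noise_sd = sim$noise_sd)
  simulate_drought_experiment(curves, replicates = sim$replicates, days = sim$days,
                              base_scene = base_scene,
                              seed = derive_seed(config$seed, 1L),
                              out_dir = out_dir, scale_range = sim$scale_range)
}

# Pick annotation images for auto patch placement: images whose true stressed
# fraction is closest to 0.5 host both classes comfortably.
pick_annotation_images <- function(truth, n_images) {
  usable <- truth[truth$true_stress_fraction > 0.05 & truth$true_stress_fraction < 0.95, ]
  if (nrow(usable) == 0) {
    stop_afpheno("no image has both stressed and non-stressed truth pixels", "placement_error")
  }
  usable[order(abs(usable$true_stress_fraction - 0.5)), ][
    seq_len(min(n_images, nrow(usable))), ]
}

#' Auto-annotate a simulated dataset
#'
#' Places ground-truth patches on the truth masks of a few mid-stress images
#' (truth fraction nearest 0.5), standing in for manual annotation.
#'
#' @param truth Truth tibble from [simulate_drought_experiment()].
#' @param root Dataset root.
#' @param config Pipeline config.
#' @return A patch tibble (see [patch_spec()]).
#' @export
auto_annotate <- function(truth, root, config = default_pipeline_config()) {
  g <- config$ground_truth
  chosen <- pick_annotation_images(truth, g$n_annotation_images)
  dplyr::bind_rows(purrr::map(seq_len(nrow(chosen)), function(i) {
    rec <- chosen[i, ]
    auto_place_patches(load_mask(file.path(root, rec$plant_mask_path)),
                       load_mask(file.path(root, rec$stress_mask_path)),
                       n_per_class = g$n_per_class, patch_radius = g$patch_radius,
                       seed = derive_seed(config$seed, 100L + i),
                       plant_id = rec$plant_id, dag = rec$dag)
  }))
}

#' Run the full stress-phenotyping pipeline
#'
#' Segments the dataset, builds the ground truth (from supplied patches or by
#' auto-annotation of a simulated dataset's truth masks), trains and compares
#' the six classifier families, classifies every image with the selected
#' model, and computes phenotypes, genotype summaries and pairwise per-day
#' Welch comparisons. Writes `accuracy_report.csv`, `phenotypes.csv`,
#' `genotype_summary.csv`, `comparisons.csv` and `run.json` under `out_dir`.
#'
#' @param manifest Manifest tibble (see [load_manifest()]).
#' @param root Dataset root directory.
#' @param config Pipeline config (see [default_pipeline_config()]).
#' @param out_dir Output directory.
#' @param patches Patch tibble, or `NULL` to auto-annotate (requires `truth`).
#' @param truth Truth tibble (simulated datasets), used when `patches` is NULL.
#' @return Invisibly, a list: `bundle`, `phenotypes`, `summary`, `comparisons`,
#'   `paths`.
#' @export
run_pipeline <- function(manifest, root, config = default_pipeline_config(),
                         out_dir, patches = NULL, truth = NULL) {
  seg <- seg_config_from(config)
  if (is.null(patches)) {
    if (is.null(truth)) {
      stop_afpheno("either patches or a truth table must be supplied", "validation_error")
    }
    patches <- auto_annotate(truth, root, config)
  }
  gt <- build_ground_truth(manifest, patches, seg, root = root)
  split <- split_ground_truth(gt, fractions = config$classifier$fractions,
                              seed = derive_seed(config$seed, 2L))
  bundle <- train_all(gt, split, classifier_specs(seed = derive_seed(config$seed, 3L)))
  pheno <- compute_phenotypes(manifest, bundle, seg, root = root,
                              window = config$phenotypes$window)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acc_path <- file.path(out_dir, "accuracy_report.csv")
  readr::write_csv(accuracy_report(bundle), acc_path, progress = FALSE)
  paths <- export_phenotype_report(pheno, out_dir)
  paths <- c(paths, accuracy_report = acc_path, run = file.path(out_dir, "run.json"))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("afpheno")),
         seed = config$seed, selected_family = bundle$selected_family,
         n_images = nrow(manifest), n_ground_truth_rows = nrow(gt),
         config = config),
    paths[["run"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bundle = bundle, phenotypes = pheno,
                 summary = genotype_average(pheno),
                 comparisons = readr::read_csv(paths[["comparisons"]],
                                               show_col_types = FALSE,
                                               progress = FALSE),
                 paths = paths))
}
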