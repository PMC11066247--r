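# Stress-based phenotypes: average percentage stress per plant and day, its
# trailing moving average, genotype summaries with standard errors, and
# per-day Welch comparisons between genotypes.

#' Percentage of stressed plant tissue
#'
#' `100 * |stressed plant pixels| / |plant pixels|`. An empty plant mask means
#' segmentation failed for the image; the value is undefined and an error is
#' raised so the record can be flagged rather than silently scored 0.
#'
#' @param stress_mask Logical stress mask.
#' @param plant_mask Logical plant mask of the same size.
#' @return A number in [0, 100].
#' @export
percentage_stress <- function(stress_mask, plant_mask) {
  stopifnot(identical(dim(stress_mask), dim(plant_mask)))
  n_plant <- sum(plant_mask)
  if (n_plant == 0) {
    stop_afpheno("plant mask is empty: percentage stress undefined", "undefined_value_error")
  }
  100 * sum(stress_mask & plant_mask) / n_plant
}

#' Trailing moving average of a phenotype series
#'
#' Value at each day is the mean of the `n` most recent observations up to and
#' including that day; at the start of the series, where fewer than `n` exist,
#' the mean of what exists. `n = 1` returns the series unchanged; the output
#' has one value per input day.
#'
#' @param values Numeric vector, ordered by DAG.
#' @param n Window size in observations (>= 1).
#' @return Numeric vector of the same length.
#' @export
moving_average_percentage_stress <- function(values, n = 3) {
  if (!is_count(n) || n < 1) stop_afpheno("window n must be a positive integer", "validation_error")
  if (length(values) == 0) return(numeric(0))
  as.numeric(zoo::rollapplyr(values, width = n, FUN = mean, partial = TRUE))
}

#' Compute per-plant, per-day stress phenotypes for a dataset
#'
#' Runs segmentation and the selected classifier over every manifest record
#' and returns the phenotype table: plant and stressed pixel counts, average
#' percentage stress, and its trailing moving average per plant. Images whose
#' segmentation is empty are flagged (`segmentation_empty = TRUE`, values NA)
#' and excluded from downstream genotype summaries, with a logged note.
#'
#' @param manifest Manifest tibble (see [load_manifest()]).
#' @param bundle A trained `stress_classifier_bundle`.
#' @param seg_config A [segmentation_config()].
#' @param root Dataset root for image paths.
#' @param window Moving-average window in days (observations), default 3.
#' @return A `stress_phenotypes` tibble: `plant_id, genotype, dag,
#'   plant_pixels, stressed_pixels, percentage_stress, moving_average,
#'   segmentation_empty`.
#' @export
compute_phenotypes <- function(manifest, bundle, seg_config = segmentation_config(),
                               root = ".", window = 3) {
  rows <- lapply(seq_len(nrow(manifest)), function(k) {
    plant_id <- manifest$plant_id[k]; genotype <- manifest$genotype[k]
    dag <- manifest$dag[k]
    image <- load_image(resolve_image_path(root, manifest$image_path[k]))
    plant <- segment_plant(image, seg_config)
    n_plant <- sum(plant)
    if (n_plant == 0) {
      inform(sprintf("plant %s dag %d: empty segmentation, record flagged", plant_id, dag))
      return(tibble::tibble(plant_id = plant_id, genotype = genotype, dag = dag,
                            plant_pixels = 0L, stressed_pixels = 0L,
                            percentage_stress = NA_real_, segmentation_empty = TRUE))
    }
    stress <- classify_image(image, plant, bundle)
    tibble::tibble(plant_id = plant_id, genotype = genotype, dag = dag,
                   plant_pixels = n_plant, stressed_pixels = sum(stress),
                   percentage_stress = percentage_stress(stress, plant),
                   segmentation_empty = FALSE)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$plant_id, .data$dag) |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::mutate(moving_average = {
      ok <- !.data$segmentation_empty
      ma <- rep(NA_real_, dplyr::n())
      if (any(ok)) {
        ma[ok] <- moving_average_percentage_stress(.data$percentage_stress[ok], n = window)
      }
      ma
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("moving_average", .after = "percentage_stress")
  class(out) <- c("stress_phenotypes", class(out))
  attr(out, "window") <- window
  out
}

#' Genotype-level daily summary
#'
#' Mean percentage stress across the replicate plants of each genotype present
#' on each day, with the standard error `sd / sqrt(n)` (reported 0 when a
#' single replicate is available). Flagged (empty-segmentation) records are
#' excluded.
#'
#' @param series A `stress_phenotypes` tibble (see [compute_phenotypes()]), or
#'   any tibble with `plant_id, genotype, dag, percentage_stress`.
#' @param genotype,dag Optional filters; with both set, exactly one summary
#'   row is returned and missing data is an error.
#' @return Tibble `genotype, dag, mean, stderr, n_replicates`.
#' @export
genotype_average <- function(series, genotype = NULL, dag = NULL) {
  df <- drop_flagged(series)
  if (!is.null(genotype)) df <- df[df$genotype %in% genotype, ]
  if (!is.null(dag)) df <- df[df$dag %in% dag, ]
  if (nrow(df) == 0) {
    stop_afpheno("no phenotype data for the requested genotype/day", "missing_data_error")
  }
  df |>
    dplyr::group_by(.data$genotype, .data$dag) |>
    dplyr::summarise(
      mean = mean(.data$percentage_stress),
      stderr = ifelse(dplyr::n() > 1, sd(.data$percentage_stress) / sqrt(dplyr::n()), 0),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$genotype, .data$dag)
}

# Exclude records flagged as empty-segmentation (column optional).
drop_flagged <- function(series) {
  if ("segmentation_empty" %in% names(series)) {
    series[!series$segmentation_empty, , drop = FALSE]
  } else {
    series
  }
}

# Welch two-sample t-test that tolerates the degenerate zero-variance case
# (identical constant groups -> p = 1; distinct constants -> p = 0).
welch_test <- function(a, b) {
  if (var(a) == 0 && var(b) == 0) {
    d <- mean(a) - mean(b)
    return(list(mean_diff = d, p_value = if (d == 0) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(mean_diff = unname(tt$estimate[1] - tt$estimate[2]), p_value = tt$p.value)
}

#' Compare two genotypes' stress levels by day
#'
#' Welch's two-sample t-test (unequal variances, two-sided) on the replicate
#' percentage-stress values of the two genotypes, per day. No multiple-testing
#' correction is applied: days are reported individually.
#'
#' @inheritParams genotype_average
#' @param genotype_a,genotype_b Genotype labels.
#' @param dag Single day, or `NULL` for every day on which both genotypes have
#'   at least 2 replicates.
#' @return Tibble `genotype_a, genotype_b, dag, mean_diff, p_value` (mean of A
#'   minus mean of B).
#' @export
compare_genotypes <- function(series, genotype_a, genotype_b, dag = NULL) {
  df <- drop_flagged(series)
  days <- if (is.null(dag)) sort(unique(df$dag)) else as.integer(dag)
  rows <- purrr::map(days, function(d) {
    a <- df$percentage_stress[df$genotype == genotype_a & df$dag == d]
    b <- df$percentage_stress[df$genotype == genotype_b & df$dag == d]
    if (length(a) < 2 || length(b) < 2) {
      if (!is.null(dag)) {
        stop_afpheno(sprintf("need >= 2 replicates per genotype at dag %d (have %d and %d)",
                             d, length(a), length(b)), "insufficient_data_error")
      }
      return(NULL)
    }
    w <- welch_test(a, b)
    tibble::tibble(genotype_a = genotype_a, genotype_b = genotype_b, dag = d,
                   mean_diff = w$mean_diff, p_value = w$p_value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    stop_afpheno("no day has >= 2 replicates for both genotypes", "insufficient_data_error")
  }
  out
}

#' Export the phenotype report
#'
#' Writes `phenotypes.csv` (per plant and day, including moving averages),
#' `genotype_summary.csv` (daily means with standard errors) and
#' `comparisons.csv` (pairwise per-day Welch tests), plus an optional
#' genotype-series line plot. Re-running on the same inputs reproduces the
#' files byte for byte.
#'
#' @param series A `stress_phenotypes` tibble.
#' @param out_dir Output directory (created).
#' @param plots If `TRUE`, also write `genotype_series.png`.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_phenotype_report <- function(series, out_dir, plots = FALSE) {
  if (nrow(series) == 0) stop_afpheno("phenotype series is empty", "validation_error")
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) stop_afpheno(paste0("cannot write to ", out_dir), "io_error")

  paths <- c(phenotypes = file.path(out_dir, "phenotypes.csv"),
             genotype_summary = file.path(out_dir, "genotype_summary.csv"),
             comparisons = file.path(out_dir, "comparisons.csv"))
  readr::write_csv(
    series[c("plant_id", "genotype", "dag", "plant_pixels", "stressed_pixels",
             "percentage_stress", "moving_average")],
    paths[["phenotypes"]], progress = FALSE)
  readr::write_csv(genotype_average(series), paths[["genotype_summary"]], progress = FALSE)

  gts <- sort(unique(series$genotype))
  comp <- if (length(gts) >= 2) {
    prs <- utils::combn(gts, 2)
    dplyr::bind_rows(purrr::map(seq_len(ncol(prs)), function(i) {
      tryCatch(compare_genotypes(series, prs[1, i], prs[2, i]),
               afpheno_insufficient_data_error = function(e) NULL)
    }))
  } else {
    tibble::tibble(genotype_a = character(0), genotype_b = character(0),
                   dag = integer(0), mean_diff = numeric(0), p_value = numeric(0))
  }
  readr::write_csv(comp, paths[["comparisons"]], progress = FALSE)

  if (plots) {
    p <- autoplot(series)
    paths <- c(paths, plot = file.path(out_dir, "genotype_series.png"))
    ggplot2::ggsave(paths[["plot"]], p, width = 7, height = 4.5, dpi = 150)
  }
  invisible(paths)
}
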