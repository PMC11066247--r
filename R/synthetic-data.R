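# Seeded synthetic autofluorescence scenes: a rosette plant on a soil/pot
# background, two separable pixel populations (stressed vs non-stressed), and
# multi-genotype progressive-drought time series with per-pixel truth masks.

#' Pixel population model
#'
#' Per-channel clipped-Gaussian intensity model for one scene label. The
#' default stressed and non-stressed populations are separated by at least
#' 4 standard deviations in one channel, which is what makes pixel-level
#' classification well-posed on synthetic scenes.
#'
#' @param mean_rgb Numeric length 3, channel means in 0-255.
#' @param std_rgb Numeric length 3, channel standard deviations (>= 0).
#' @param label One of `"non_stressed"`, `"stressed"`, `"background_soil"`,
#'   `"background_pot"`.
#' @return A `pixel_population` list.
#' @export
pixel_population <- function(mean_rgb, std_rgb, label) {
  stopifnot(length(mean_rgb) == 3L, length(std_rgb) == 3L)
  if (any(mean_rgb < 0) || any(mean_rgb > 255) || any(std_rgb < 0)) {
    stop_afpheno("population means must be in [0,255] and stds >= 0", "validation_error")
  }
  label <- match.arg(label, c("non_stressed", "stressed", "background_soil", "background_pot"))
  structure(list(mean_rgb = as.numeric(mean_rgb), std_rgb = as.numeric(std_rgb),
                 label = label), class = "pixel_population")
}

#' Default scene pixel populations
#'
#' Non-stressed tissue fluoresces red (chlorophyll emission dominates);
#' stressed, chlorophyll-depleted tissue appears brown-yellow (high red and
#' green); soil is dim brown and the pot ring darker still.
#'
#' @return Named list of four [pixel_population()] objects.
#' @export
default_populations <- function() {
  list(
    non_stressed   = pixel_population(c(170, 60, 50),  c(12, 12, 12), "non_stressed"),
    stressed       = pixel_population(c(215, 150, 55), c(12, 12, 12), "stressed"),
    background_soil = pixel_population(c(60, 45, 35),  c(10, 10, 10), "background_soil"),
    background_pot  = pixel_population(c(30, 30, 32),  c(6, 6, 6),   "background_pot")
  )
}

#' Channel separation between two pixel populations
#'
#' Maximum over channels of |mean difference| / max(std), the "sigma
#' separation" used to check that the stressed and non-stressed classes are
#' statistically separable (>= 4 under the default configuration).
#'
#' @param pop_a,pop_b [pixel_population()] objects.
#' @return A single number.
#' @export
population_separation <- function(pop_a, pop_b) {
  s <- pmax(pop_a$std_rgb, pop_b$std_rgb)
  s[s == 0] <- .Machine$double.eps
  max(abs(pop_a$mean_rgb - pop_b$mean_rgb) / s)
}

#' Synthetic scene configuration
#'
#' @param height,width Image size in pixels.
#' @param center Plant center `(row, col)`; defaults to the image center.
#' @param n_leaves Number of rosette leaves (>= 1).
#' @param leaf_length_range Range of leaf semi-major axis at scale 1, pixels.
#' @param leaf_width_ratio_range Range of semi-minor / semi-major ratio.
#' @param scale Linear plant size multiplier (growth proxy).
#' @param stress_fraction Target fraction of plant pixels stressed, in [0,1].
#' @param populations Named list of the four [pixel_population()] models.
#' @param noise_sd Additive per-pixel Gaussian noise, intensity units.
#' @param pot_radius,pot_width Pot ring geometry, pixels.
#' @param seed Integer RNG seed; the whole scene is a deterministic function
#'   of the configuration.
#' @return A `scene_config` list.
#' @export
scene_config <- function(height = 160, width = 160, center = NULL,
                         n_leaves = 8, leaf_length_range = c(34, 50),
                         leaf_width_ratio_range = c(0.32, 0.45), scale = 1,
                         stress_fraction = 0, populations = default_populations(),
                         noise_sd = 4, pot_radius = NULL, pot_width = 4,
                         seed = 1) {
  if (!is.numeric(stress_fraction) || stress_fraction < 0 || stress_fraction > 1) {
    stop_afpheno("stress_fraction must lie in [0, 1]", "validation_error")
  }
  if (!is_count(n_leaves) || n_leaves < 1) {
    stop_afpheno("n_leaves must be a positive integer", "validation_error")
  }
  center <- center %||% c((height - 1) / 2, (width - 1) / 2)
  pot_radius <- pot_radius %||% (0.47 * min(height, width))
  cfg <- structure(list(
    height = as.integer(height), width = as.integer(width), center = center,
    n_leaves = as.integer(n_leaves), leaf_length_range = leaf_length_range,
    leaf_width_ratio_range = leaf_width_ratio_range, scale = scale,
    stress_fraction = stress_fraction, populations = populations,
    noise_sd = noise_sd, pot_radius = pot_radius, pot_width = pot_width,
    seed = as.integer(seed)
  ), class = "scene_config")
  sep <- population_separation(populations$stressed, populations$non_stressed)
  if (sep < 4) {
    warn(sprintf(paste0("stressed / non-stressed populations are only %.1f sigma apart ",
                        "(< 4): pixel classes may not be separable"), sep))
  }
  if (max(leaf_length_range) * scale * 1.15 > min(height, width) / 2) {
    stop_afpheno("plant does not fit in the image at this scale", "geometry_error")
  }
  cfg
}

#' Draw pixel feature vectors from a population model
#'
#' i.i.d. per-channel Gaussians, clipped to [0, 255]; deterministic given
#' `seed`.
#'
#' @param model A [pixel_population()].
#' @param n Number of pixels (>= 0).
#' @param seed Integer RNG seed.
#' @return An `n x 3` numeric matrix with columns `r`, `g`, `b`.
#' @export
sample_pixels <- function(model, n, seed = 1) {
  if (!is_count(n)) stop_afpheno("n must be a non-negative integer", "validation_error")
  out <- with_seed(seed, {
    m <- matrix(0, nrow = n, ncol = 3)
    for (ch in 1:3) {
      m[, ch] <- rnorm(n, model$mean_rgb[ch], model$std_rgb[ch])
    }
    m
  })
  out <- pmin(pmax(out, 0), 255)
  colnames(out) <- c("r", "g", "b")
  out
}

# Logical mask of lattice points inside a rotated ellipse. `a` is the semi-axis
# along the orientation direction (column axis at 0 degrees), `b` across it.
ellipse_mask <- function(height, width, center, a, b, orientation_deg = 0) {
  th <- orientation_deg * pi / 180
  rows <- matrix(0:(height - 1), nrow = height, ncol = width)
  cols <- matrix(0:(width - 1), nrow = height, ncol = width, byrow = TRUE)
  dr <- rows - center[1]
  dc <- cols - center[2]
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Grow a contiguous stressed region from a leaf-tip seed by breadth-first
# accretion over the 4-neighbourhood until exactly `target` plant pixels are
# collected. Deterministic given the RNG state.
grow_stress_region <- function(plant_mask, target, center) {
  h <- nrow(plant_mask); w <- ncol(plant_mask)
  n_plant <- sum(plant_mask)
  if (target <= 0) return(matrix(FALSE, h, w))
  if (target >= n_plant) return(plant_mask)
  idx <- which(plant_mask)
  rows <- (idx - 1) %% h + 1
  cols <- (idx - 1) %/% h + 1
  d2 <- (rows - 1 - center[1])^2 + (cols - 1 - center[2])^2
  # seed at a leaf tip: a random pixel among the 5% farthest from the center
  tips <- idx[d2 >= stats::quantile(d2, 0.95)]
  seed_px <- tips[sample.int(length(tips), 1)]
  visited <- matrix(FALSE, h, w)
  selected <- integer(0)
  frontier <- seed_px
  visited[seed_px] <- TRUE
  while (length(selected) < target) {
    if (length(frontier) == 0) {
      # plant mask disconnected: restart from the first unvisited plant pixel
      remaining <- idx[!visited[idx]]
      frontier <- remaining[1]
      visited[frontier] <- TRUE
    }
    take <- min(length(frontier), target - length(selected))
    selected <- c(selected, sort(frontier)[seq_len(take)])
    if (length(selected) >= target) break
    fr <- (frontier - 1) %% h + 1
    fc <- (frontier - 1) %/% h + 1
    nb_r <- c(fr - 1, fr + 1, fr, fr)
    nb_c <- c(fc, fc, fc - 1, fc + 1)
    ok <- nb_r >= 1 & nb_r <= h & nb_c >= 1 & nb_c <= w
    nb <- unique((nb_c[ok] - 1) * h + nb_r[ok])
    nb <- nb[plant_mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  out <- matrix(FALSE, h, w)
  out[selected] <- TRUE
  out
}

#' Render one synthetic autofluorescence scene
#'
#' Draws a rosette (overlapping filled ellipses around a central disc) on a
#' soil background with a darker pot ring, relabels a contiguous region of
#' plant pixels as stressed so the realised stressed fraction equals
#' `round(stress_fraction * plant pixels)` (within 1 percentage point of the
#' target, and exactly 0 or 1 at the extremes), and samples pixel intensities
#' from the four population models. Deterministic given the configuration.
#'
#' @param config A [scene_config()].
#' @return A list with elements `image` ([fl_image()]), `plant_mask` and
#'   `stress_mask` (logical matrices; the stress mask is a subset of the plant
#'   mask), and `stress_fraction_realized`.
#' @export
render_plant_image <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$height; w <- config$width; ctr <- config$center
  with_seed(config$seed, {
    plant <- matrix(FALSE, h, w)
    # central disc keeps the rosette connected
    core_r <- max(2, 0.16 * max(config$leaf_length_range) * config$scale)
    plant <- plant | ellipse_mask(h, w, ctr, core_r, core_r)
    angles <- seq(0, 2 * pi, length.out = config$n_leaves + 1)[-(config$n_leaves + 1)]
    angles <- angles + runif(config$n_leaves, -0.12, 0.12)
    for (k in seq_len(config$n_leaves)) {
      len <- runif(1, config$leaf_length_range[1], config$leaf_length_range[2]) * config$scale
      wid <- len * runif(1, config$leaf_width_ratio_range[1], config$leaf_width_ratio_range[2])
      a <- len * 0.55
      lc <- c(ctr[1] + sin(angles[k]) * len * 0.55, ctr[2] + cos(angles[k]) * len * 0.55)
      plant <- plant | ellipse_mask(h, w, lc, a, wid, orientation_deg = angles[k] * 180 / pi)
    }
    n_plant <- sum(plant)
    target <- round(config$stress_fraction * n_plant)
    stress <- grow_stress_region(plant, target, ctr)

    # pot ring: annulus around the plant, then soil everywhere else
    rr <- sqrt((matrix(0:(h - 1), h, w) - ctr[1])^2 +
                 (matrix(0:(w - 1), h, w, byrow = TRUE) - ctr[2])^2)
    pot <- rr >= config$pot_radius - config$pot_width & rr <= config$pot_radius & !plant

    px <- array(0, dim = c(h, w, 3))
    pops <- config$populations
    fill <- function(px, mask, pop) {
      n <- sum(mask)
      if (n == 0) return(px)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[mask] <- rnorm(n, pop$mean_rgb[ch], pop$std_rgb[ch])
        px[, , ch] <- plane
      }
      px
    }
    px <- fill(px, !plant & !pot, pops$background_soil)
    px <- fill(px, pot, pops$background_pot)
    px <- fill(px, plant & !stress, pops$non_stressed)
    px <- fill(px, stress, pops$stressed)
    if (config$noise_sd > 0) px <- px + rnorm(length(px), 0, config$noise_sd)
    px <- pmin(pmax(px, 0), 255)
    list(
      image = fl_image(round(px)),
      plant_mask = plant,
      stress_mask = stress,
      stress_fraction_realized = if (n_plant > 0) sum(stress) / n_plant else NA_real_
    )
  })
}

#' Genotype drought-response curve
#'
#' Stressed tissue fraction as a function of day after germination (DAG):
#' zero before the stress onset day, then a rescaled logistic rise
#' `plateau_level * (S(d) - S(onset)) / (1 - S(onset))` with
#' `S(d) = 1 / (1 + exp(-rate * (d - inflection_day)))`. The curve is monotone
#' non-decreasing and bounded by `plateau_level`. The `logistic_plateau`
#' family (fast rate, early inflection) saturates mid-experiment; the
#' `logistic` family (slow rate, late inflection) is still rising at the end.
#'
#' @param genotype Genotype label.
#' @param onset_day Stress onset DAG (`ti`); 0 means never stressed.
#' @param family `"logistic_plateau"` or `"logistic"` (presets of one formula).
#' @param plateau_level Asymptotic stressed fraction in [0, 1].
#' @param rate Logistic rate per day.
#' @param inflection_day Logistic inflection DAG.
#' @param replicate_noise_std Per-image Gaussian noise on the fraction scale.
#' @return A `drought_curve` list.
#' @export
drought_curve <- function(genotype, onset_day = 10,
                          family = c("logistic_plateau", "logistic"),
                          plateau_level = 0.15, rate = 0.9, inflection_day = 13,
                          replicate_noise_std = 0.02) {
  family <- match.arg(family)
  if (plateau_level < 0 || plateau_level > 1) {
    stop_afpheno("plateau_level must lie in [0, 1]", "validation_error")
  }
  if (!is_count(onset_day)) stop_afpheno("onset_day must be a non-negative integer", "validation_error")
  structure(list(genotype = genotype, onset_day = as.integer(onset_day),
                 family = family, plateau_level = plateau_level, rate = rate,
                 inflection_day = inflection_day,
                 replicate_noise_std = replicate_noise_std),
            class = "drought_curve")
}

#' Evaluate a drought curve
#'
#' @param curve A [drought_curve()].
#' @param dag Vector of days after germination.
#' @return Stressed fraction(s) in `[0, plateau_level]`.
#' @export
curve_value <- function(curve, dag) {
  stopifnot(inherits(curve, "drought_curve"))
  if (curve$onset_day == 0) return(rep(0, length(dag)))  # never stressed
  S <- function(d) 1 / (1 + exp(-curve$rate * (d - curve$inflection_day)))
  s0 <- S(curve$onset_day)
  v <- curve$plateau_level * (S(dag) - s0) / (1 - s0)
  v[dag < curve$onset_day] <- 0
  pmin(pmax(v, 0), curve$plateau_level)
}

#' Default genotype drought curves
#'
#' Three-genotype configuration emulating a drought-tolerant oilseed-type
#' genotype whose stressed fraction plateaus around 15% and two susceptible
#' genotypes whose tissue damage keeps increasing through the experiment.
#'
#' @param onset_day Stress onset DAG for all genotypes.
#' @return Named list of three [drought_curve()] objects.
#' @export
default_genotype_curves <- function(onset_day = 10) {
  list(
    R500 = drought_curve("R500", onset_day, "logistic_plateau",
                         plateau_level = 0.15, rate = 0.9, inflection_day = 13),
    CC = drought_curve("CC", onset_day, "logistic",
                       plateau_level = 0.55, rate = 0.25, inflection_day = 22),
    VT = drought_curve("VT", onset_day, "logistic",
                       plateau_level = 0.60, rate = 0.22, inflection_day = 21)
  )
}

#' Simulate a progressive-drought imaging experiment
#'
#' Renders one synthetic image per (genotype, replicate, day), with per-image
#' stressed fraction `curve(dag) + replicate noise` (clipped to [0, 1]) and
#' plant size growing linearly with DAG. Writes the images, per-pixel truth
#' masks (plant and stressed regions, 0/255 PNGs), the dataset manifest CSV
#' and a truth CSV under `out_dir`. Fully reproducible from `seed`.
#'
#' @param curves List of [drought_curve()] objects, one per genotype
#'   (duplicate genotype labels are rejected).
#' @param replicates Replicate plants per genotype (>= 1).
#' @param days Integer vector of imaging days (DAG), non-empty.
#' @param base_scene A [scene_config()] providing geometry, populations, noise.
#' @param seed Integer seed for the whole experiment.
#' @param out_dir Output directory (created).
#' @param scale_range Plant scale at the first and last day; linear in DAG.
#' @return A list with `manifest` (tibble, see [load_manifest()]), `truth`
#'   (tibble: plant_id, genotype, dag, true_stress_fraction, plant_mask_path,
#'   stress_mask_path) and `root = out_dir`.
#' @export
simulate_drought_experiment <- function(curves, replicates = 6, days = 5:30,
                                        base_scene = scene_config(),
                                        seed = 1, out_dir,
                                        scale_range = c(0.35, 1)) {
  labels <- vapply(curves, function(cu) cu$genotype, character(1))
  if (anyDuplicated(labels) > 0) {
    stop_afpheno("duplicate genotype labels in curves", "validation_error")
  }
  if (replicates < 1) stop_afpheno("replicates must be >= 1", "validation_error")
  if (length(days) == 0) stop_afpheno("days must be non-empty", "validation_error")
  days <- sort(unique(as.integer(days)))
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)

  grid <- tidyr::expand_grid(genotype = labels, replicate = seq_len(replicates),
                             dag = days)
  grid$i <- seq_len(nrow(grid))
  day_span <- max(days) - min(days)
  rows <- purrr::pmap(grid, function(genotype, replicate, dag, i) {
    cu <- curves[[match(genotype, labels)]]
    img_seed <- derive_seed(seed, i)
    frac <- with_seed(derive_seed(seed, i + nrow(grid)),
                      curve_value(cu, dag) + rnorm(1, 0, cu$replicate_noise_std))
    frac <- min(max(frac, 0), 1)
    scale <- if (day_span == 0) scale_range[2] else
      scale_range[1] + (scale_range[2] - scale_range[1]) * (dag - min(days)) / day_span
    cfg <- base_scene
    cfg$scale <- scale
    cfg$stress_fraction <- frac
    cfg$seed <- img_seed
    scene <- render_plant_image(cfg)
    plant_id <- sprintf("%s_%02d", genotype, replicate)
    stem <- sprintf("%s_dag%02d", plant_id, dag)
    image_path <- file.path("images", paste0(stem, ".png"))
    plant_mask_path <- file.path("truth", paste0(stem, "_plant.png"))
    stress_mask_path <- file.path("truth", paste0(stem, "_stress.png"))
    save_image(scene$image, file.path(out_dir, image_path))
    save_mask(scene$plant_mask, file.path(out_dir, plant_mask_path))
    save_mask(scene$stress_mask, file.path(out_dir, stress_mask_path))
    tibble::tibble(
      plant_id = plant_id, genotype = genotype, dag = dag,
      stress_onset_day = cu$onset_day, image_path = image_path,
      true_stress_fraction = scene$stress_fraction_realized,
      plant_mask_path = plant_mask_path, stress_mask_path = stress_mask_path
    )
  })
  all <- dplyr::bind_rows(rows)
  manifest <- validate_manifest_tbl(all[manifest_columns])
  truth <- dplyr::arrange(
    all[c("plant_id", "genotype", "dag", "true_stress_fraction",
          "plant_mask_path", "stress_mask_path")],
    .data$plant_id, .data$dag)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  readr::write_csv(truth, file.path(out_dir, "truth.csv"), progress = FALSE)
  list(manifest = manifest, truth = truth, root = out_dir)
}

#' Write / read a binary mask as a 0/255 grayscale PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `save_mask`: the path invisibly; `load_mask`: a logical matrix.
#' @export
save_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop_afpheno(paste0("mask not found: ", path), "not_found_error")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}
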