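# Pixel-level ground truth from annotated leaf patches. Annotators (or, for
# synthetic data, the truth masks) place circular patches on healthy tissue
# and oval patches on dried tissue; every patch pixel that falls inside the
# segmented plant region contributes one labelled (r, g, b) row.

patch_columns <- c("plant_id", "dag", "row", "col", "a", "b",
                   "orientation_deg", "label")

#' Build a patch annotation table
#'
#' One row per patch: center `(row, col)` (0-based pixel coordinates), ellipse
#' semi-axes `a` (along the orientation direction; the column axis at 0
#' degrees) and `b`, orientation in degrees, and the class label. Circles are
#' ellipses with `a == b`.
#'
#' @param plant_id,dag Which image the patch annotates.
#' @param row,col Patch center, 0-based.
#' @param a,b Semi-axes in pixels (>= 1).
#' @param orientation_deg Rotation of the `a` axis, degrees.
#' @param label `"non_stressed"` or `"stressed"`.
#' @return A patch tibble.
#' @export
patch_spec <- function(plant_id, dag, row, col, a, b = a, orientation_deg = 0,
                       label) {
  if (any(a < 1) || any(b < 1)) {
    stop_afpheno("patch semi-axes must be >= 1 pixel", "validation_error")
  }
  if (!all(label %in% pixel_classes())) {
    stop_afpheno("patch label must be 'non_stressed' or 'stressed'", "validation_error")
  }
  tibble::tibble(plant_id = as.character(plant_id), dag = as.integer(dag),
                 row = row, col = col, a = a, b = b,
                 orientation_deg = orientation_deg, label = label)
}

#' Read / write patch annotation CSVs
#'
#' CSV columns: `plant_id,dag,row,col,a,b,orientation_deg,label`.
#'
#' @param path CSV path.
#' @return A patch tibble (see [patch_spec()]).
#' @export
load_patches <- function(path) {
  if (!file.exists(path)) stop_afpheno(paste0("patch file not found: ", path), "not_found_error")
  p <- readr::read_csv(path, col_types = readr::cols(
    plant_id = readr::col_character(), dag = readr::col_integer(),
    row = readr::col_double(), col = readr::col_double(),
    a = readr::col_double(), b = readr::col_double(),
    orientation_deg = readr::col_double(), label = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(patch_columns, names(p))
  if (length(missing_cols) > 0) {
    stop_afpheno(paste0("patch CSV missing column(s): ",
                        paste(missing_cols, collapse = ", ")), "schema_error")
  }
  patch_spec(p$plant_id, p$dag, p$row, p$col, p$a, p$b, p$orientation_deg, p$label)
}

#' @rdname load_patches
#' @param patches A patch tibble.
#' @export
save_patches <- function(patches, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(patches[patch_columns], path, progress = FALSE)
  invisible(path)
}

# Linear indices of lattice points inside one patch ellipse, clipped to the
# image extent.
patch_pixel_index <- function(height, width, patch_row) {
  m <- ellipse_mask(height, width, c(patch_row$row, patch_row$col),
                    patch_row$a, patch_row$b, patch_row$orientation_deg)
  which(m)
}

#' Extract labelled pixels under one patch
#'
#' Returns the (r, g, b) triple of every pixel inside the patch ellipse AND
#' inside the plant mask, tagged with the patch label. Pixels outside the mask
#' contribute nothing; a patch that misses the mask entirely yields a warning
#' and zero rows.
#'
#' @param image An [fl_image()].
#' @param mask Logical plant mask of matching size.
#' @param patch One-row patch tibble (see [patch_spec()]).
#' @return Tibble with columns `r, g, b, label, plant_id, dag`.
#' @export
extract_patch_pixels <- function(image, mask, patch) {
  stopifnot(is_fl_image(image), nrow(patch) == 1L)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (patch$row < 0 || patch$row > h - 1 || patch$col < 0 || patch$col > w - 1) {
    stop_afpheno("patch center lies outside the image", "validation_error")
  }
  idx <- patch_pixel_index(h, w, patch)
  idx <- idx[mask[idx]]
  if (length(idx) == 0) {
    warn(sprintf("patch at (%g, %g) does not intersect the plant mask; 0 pixels",
                 patch$row, patch$col))
  }
  tibble::tibble(
    r = as.integer(image[, , 1][idx]),
    g = as.integer(image[, , 2][idx]),
    b = as.integer(image[, , 3][idx]),
    label = rep(patch$label, length(idx)),
    plant_id = rep(patch$plant_id, length(idx)),
    dag = rep(patch$dag, length(idx))
  )
}

#' Build the ground-truth pixel table
#'
#' Segments every image referenced by the patch table and concatenates the
#' labelled pixel rows of all patches. The result is the ground-truth dataset
#' G: the union of the non-stressed and stressed pixel sets, each pixel
#' contributing one row. Both classes must end up non-empty.
#'
#' @param manifest Manifest tibble (see [load_manifest()]).
#' @param patches Patch tibble (see [patch_spec()]).
#' @param seg_config A [segmentation_config()].
#' @param root Dataset root for the manifest's image paths.
#' @return Tibble `r, g, b, label, plant_id, dag` with a per-class count
#'   attribute `class_counts`.
#' @export
build_ground_truth <- function(manifest, patches, seg_config = segmentation_config(),
                               root = ".") {
  if (nrow(patches) == 0) stop_afpheno("no patches supplied", "validation_error")
  keys <- dplyr::distinct(patches, .data$plant_id, .data$dag)
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    plant_id <- keys$plant_id[k]; dag <- keys$dag[k]
    rec <- manifest[manifest$plant_id == plant_id & manifest$dag == dag, ]
    if (nrow(rec) == 0) {
      stop_afpheno(sprintf("no manifest record for plant '%s' at dag %d", plant_id, dag),
                   "not_found_error")
    }
    image <- load_image(resolve_image_path(root, rec$image_path[1]))
    mask <- segment_plant(image, seg_config)
    pp <- patches[patches$plant_id == plant_id & patches$dag == dag, ]
    purrr::map(seq_len(nrow(pp)),
               function(i) extract_patch_pixels(image, mask, pp[i, ]))
  })
  gt <- dplyr::bind_rows(purrr::flatten(rows))
  counts <- table(factor(gt$label, levels = pixel_classes()))
  for (cl in pixel_classes()) {
    if (counts[[cl]] == 0) {
      stop_afpheno(paste0("ground truth has zero pixels for class '", cl, "'"),
                   "validation_error")
    }
  }
  attr(gt, "class_counts") <- as.integer(counts)
  names(attr(gt, "class_counts")) <- pixel_classes()
  gt
}

#' Automatically place patches from truth masks (synthetic data)
#'
#' Stands in for manual annotation when per-pixel truth is available: places
#' `n_per_class` circular patches per class, fully inside the corresponding
#' truth region and pairwise non-overlapping, by seeded rejection sampling.
#' When a region cannot host the requested count the function falls back to
#' the patches it found, with a warning.
#'
#' @param plant_mask,stress_mask Logical truth masks (stress subset of plant).
#' @param n_per_class Patches per class (>= 0).
#' @param patch_radius Patch radius in pixels.
#' @param seed Integer RNG seed.
#' @param plant_id,dag Metadata copied onto the patch rows.
#' @return A patch tibble (see [patch_spec()]).
#' @export
auto_place_patches <- function(plant_mask, stress_mask, n_per_class = 4,
                               patch_radius = 4, seed = 1,
                               plant_id = NA_character_, dag = NA_integer_) {
  if (!is_count(n_per_class)) stop_afpheno("n_per_class must be >= 0", "validation_error")
  if (n_per_class == 0) return(patch_spec(character(0), integer(0), numeric(0),
                                          numeric(0), numeric(0), numeric(0),
                                          numeric(0), character(0)))
  regions <- list(non_stressed = plant_mask & !stress_mask, stressed = stress_mask)
  h <- nrow(plant_mask); w <- ncol(plant_mask)
  with_seed(seed, {
    out <- list()
    taken <- matrix(FALSE, h, w)
    for (cl in pixel_classes()) {
      region <- regions[[cl]]
      cand <- which(region)
      if (length(cand) == 0) {
        stop_afpheno(paste0("truth region for class '", cl, "' is empty"),
                     "placement_error")
      }
      placed <- 0L
      tries <- 0L
      max_tries <- 400L * n_per_class
      while (placed < n_per_class && tries < max_tries) {
        tries <- tries + 1L
        ci <- cand[sample.int(length(cand), 1)]
        pr <- (ci - 1) %% h
        pc <- (ci - 1) %/% h
        idx <- patch_pixel_index(h, w, list(row = pr, col = pc, a = patch_radius,
                                            b = patch_radius, orientation_deg = 0))
        # full containment in the class region and no overlap with earlier patches
        if (all(region[idx]) && !any(taken[idx])) {
          taken[idx] <- TRUE
          out[[length(out) + 1L]] <- patch_spec(plant_id, dag, pr, pc,
                                                patch_radius, patch_radius, 0, cl)
          placed <- placed + 1L
        }
      }
      if (placed < n_per_class) {
        warn(sprintf("class '%s': placed only %d of %d requested patches", cl,
                     placed, n_per_class))
      }
      if (placed == 0) {
        stop_afpheno(paste0("could not place any patch for class '", cl, "'"),
                     "placement_error")
      }
    }
    dplyr::bind_rows(out)
  })
}
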