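# Colour-threshold plant segmentation with age-dependent channel selection.
# Small, young plants are close in intensity to the soil and segment better in
# HSV; grown plants are reliably red-dominant, so the red channel separates
# plant from background. `auto` mode switches on mask area.

#' Segmentation configuration
#'
#' Thresholds are calibrated against the default synthetic pixel populations
#' and are all overridable. In `hsv` mode a pixel is foreground iff its HSV
#' triple lies inside the configured bounds; in `rgb_red` mode iff
#' `red >= red_threshold` and red exceeds both other channels by
#' `red_margin`. `auto` segments with HSV first and re-segments with the red
#' rule when the HSV mask exceeds `auto_switch_area` pixels.
#'
#' @param mode `"auto"`, `"hsv"` or `"rgb_red"`.
#' @param hue_range Hue bounds in degrees. A negative lower bound wraps around
#'   red: `c(-40, 80)` accepts hues in \[320, 360) and \[0, 80\].
#' @param saturation_range,value_range Bounds in [0, 1].
#' @param red_threshold Minimum red intensity (0-255).
#' @param red_margin Required red excess over green and blue (0-255).
#' @param min_component_area Connected components (8-connectivity) smaller
#'   than this are removed.
#' @param morphology_radius Disc radius for morphological opening; 0 disables.
#' @param auto_switch_area HSV-mask pixel count above which `auto` mode uses
#'   the red-channel rule.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(mode = c("auto", "hsv", "rgb_red"),
                                hue_range = c(-40, 80),
                                saturation_range = c(0.30, 1),
                                value_range = c(0.35, 1),
                                red_threshold = 110, red_margin = 20,
                                min_component_area = 15,
                                morphology_radius = 1,
                                auto_switch_area = 1500) {
  mode <- match.arg(mode)
  if (min_component_area < 0 || morphology_radius < 0) {
    stop_afpheno("min_component_area and morphology_radius must be >= 0", "config_error")
  }
  if (red_threshold < 0 || red_threshold > 255 || red_margin < 0 || red_margin > 255) {
    stop_afpheno("red thresholds must lie in [0, 255]", "config_error")
  }
  if (hue_range[1] < -180 || hue_range[2] >= 360 || hue_range[1] > hue_range[2] ||
      any(saturation_range < 0) || any(saturation_range > 1) ||
      any(value_range < 0) || any(value_range > 1)) {
    stop_afpheno("HSV bounds out of channel range", "config_error")
  }
  structure(list(mode = mode, hue_range = hue_range,
                 saturation_range = saturation_range, value_range = value_range,
                 red_threshold = red_threshold, red_margin = red_margin,
                 min_component_area = min_component_area,
                 morphology_radius = morphology_radius,
                 auto_switch_area = auto_switch_area),
            class = "segmentation_config")
}

#' Convert 8-bit RGB values to HSV
#'
#' Standard hexcone conversion. Hue is in degrees [0, 360); saturation and
#' value in [0, 1].
#'
#' @param rgb Length-3 vector or `n x 3` matrix of intensities in 0-255.
#' @return `n x 3` matrix with columns `h`, `s`, `v` (a 1-row matrix for a
#'   single pixel).
#' @export
rgb_to_hsv <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3, byrow = FALSE)
  if (any(rgb < 0) || any(rgb > 255)) {
    stop_afpheno("channels must lie in [0, 255]", "validation_error")
  }
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  out <- cbind(h = (hsv[, 1] * 360) %% 360, s = hsv[, 2], v = hsv[, 3])
  out
}

# Raw threshold rules, before noise removal; exposed for the brute-force
# equivalence tests.
threshold_mask <- function(image, config, mode) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  if (mode == "rgb_red") {
    r >= config$red_threshold & (r - g) >= config$red_margin &
      (r - b) >= config$red_margin
  } else if (mode == "hsv") {
    hsv <- rgb_to_hsv(cbind(as.vector(r), as.vector(g), as.vector(b)))
    hue_ok <- if (config$hue_range[1] < 0) {
      hsv[, 1] >= 360 + config$hue_range[1] | hsv[, 1] <= config$hue_range[2]
    } else {
      hsv[, 1] >= config$hue_range[1] & hsv[, 1] <= config$hue_range[2]
    }
    m <- hue_ok &
      hsv[, 2] >= config$saturation_range[1] & hsv[, 2] <= config$saturation_range[2] &
      hsv[, 3] >= config$value_range[1] & hsv[, 3] <= config$value_range[2]
    matrix(m, nrow(r), ncol(r))
  } else {
    stop_afpheno(paste0("unknown segmentation mode: ", mode), "config_error")
  }
}

#' Segment the plant region of an autofluorescence image
#'
#' Applies the configured colour-threshold rule (see
#' [segmentation_config()]), then [remove_noise()]. Deterministic.
#'
#' @param image An [fl_image()].
#' @param config A [segmentation_config()].
#' @return Logical plant mask, same height and width as the image.
#' @export
segment_plant <- function(image, config = segmentation_config()) {
  stopifnot(is_fl_image(image), inherits(config, "segmentation_config"))
  mask <- if (config$mode == "auto") {
    m <- threshold_mask(image, config, "hsv")
    if (sum(m) > config$auto_switch_area) threshold_mask(image, config, "rgb_red") else m
  } else {
    threshold_mask(image, config, config$mode)
  }
  remove_noise(mask, config)
}

# 8-connected component labelling: EBImage's 4-connected labels merged across
# diagonal adjacencies with a union-find.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(pairs)
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Remove segmentation noise from a binary mask
#'
#' Morphological opening with a disc of the configured radius (the radius-1
#' disc is the full 3 x 3 neighbourhood), followed by removal of 8-connected
#' components smaller than `min_component_area` pixels. The output is a subset
#' of the input; the operation is idempotent when the opening radius is 0.
#'
#' @param mask Logical matrix.
#' @inheritParams segment_plant
#' @return Logical matrix of the same size.
#' @export
remove_noise <- function(mask, config = segmentation_config()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(mask)
  m <- mask
  if (config$morphology_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(config$morphology_radius) + 1L,
                                shape = "disc")
    m <- EBImage::opening(matrix(as.numeric(m), nrow(m), ncol(m)), brush) > 0.5
  }
  if (config$min_component_area > 0 && any(m)) {
    lab <- label_components_8(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= config$min_component_area)
    m <- matrix(lab %in% keep & lab > 0, nrow(m), ncol(m))
  }
  m
}

#' Jaccard index between two binary masks
#'
#' Intersection over union; 1 when both masks are empty.
#'
#' @param a,b Logical matrices of equal size.
#' @return A number in [0, 1].
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
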