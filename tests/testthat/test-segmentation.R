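# Brute-force oracles for the threshold rules and morphology, independent of
# the implementation's vectorised path.

brute_force_rgb_red <- function(image, config) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      r <- image[i, j, 1]; g <- image[i, j, 2]; b <- image[i, j, 3]
      out[i, j] <- r >= config$red_threshold &&
        (r - g) >= config$red_margin && (r - b) >= config$red_margin
    }
  }
  out
}

brute_force_hsv <- function(image, config) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      hsv <- rgb_to_hsv(c(image[i, j, 1], image[i, j, 2], image[i, j, 3]))
      hue_ok <- if (config$hue_range[1] < 0) {
        hsv[1] >= 360 + config$hue_range[1] || hsv[1] <= config$hue_range[2]
      } else {
        hsv[1] >= config$hue_range[1] && hsv[1] <= config$hue_range[2]
      }
      out[i, j] <- hue_ok &&
        hsv[2] >= config$saturation_range[1] && hsv[2] <= config$saturation_range[2] &&
        hsv[3] >= config$value_range[1] && hsv[3] <= config$value_range[2]
    }
  }
  out
}

# Opening with the full 3x3 box (radius-1 disc): erosion then dilation.
# Border convention: out-of-image neighbours count as foreground for erosion
# and background for dilation, so shapes touching the border are not eaten.
brute_force_opening_3x3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(TRUE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  er <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    er[i, j] <- all(pad[i:(i + 2), j:(j + 2)])
  }
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- er
  di <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    di[i, j] <- any(pad[i:(i + 2), j:(j + 2)])
  }
  di
}

test_that("rgb_to_hsv matches the hexcone convention on reference colours", {
  expect_equal(as.numeric(rgb_to_hsv(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(as.numeric(rgb_to_hsv(c(255, 0, 0))), c(0, 1, 1))
  expect_equal(as.numeric(rgb_to_hsv(c(0, 128, 0))), c(120, 1, 128 / 255))
  # hue stays in [0, 360)
  x <- withr::with_seed(4, matrix(sample(0:255, 300, TRUE), ncol = 3))
  hsv <- rgb_to_hsv(x)
  expect_true(all(hsv[, 1] >= 0 & hsv[, 1] < 360))
  expect_true(all(hsv[, 2:3] >= 0 & hsv[, 2:3] <= 1))
})

test_that("segment_plant equals per-pixel brute-force thresholding on small images", {
  cfg_red <- segmentation_config(mode = "rgb_red", min_component_area = 0,
                                 morphology_radius = 0)
  cfg_hsv <- segmentation_config(mode = "hsv", min_component_area = 0,
                                 morphology_radius = 0)
  for (s in 1:5) {
    img <- fl_image(withr::with_seed(s, array(sample(0:255, 24 * 32 * 3, TRUE),
                                              dim = c(24, 32, 3))))
    expect_identical(segment_plant(img, cfg_red), brute_force_rgb_red(img, cfg_red))
    expect_identical(segment_plant(img, cfg_hsv), brute_force_hsv(img, cfg_hsv))
  }
})

test_that("an all-background scene segments to an empty mask", {
  sc <- render_plant_image(small_scene(seed = 3))
  img <- sc$image
  # blank out the plant with soil-coloured pixels
  soil <- default_populations()$background_soil
  px <- unclass(img)
  idx <- which(sc$plant_mask)
  fillpx <- sample_pixels(soil, length(idx), seed = 8)
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[idx] <- round(fillpx[, ch])
    px[, , ch] <- plane
  }
  mask <- segment_plant(fl_image(px))
  expect_identical(sum(mask), 0L)
})

test_that("a fully red-dominant image saturates the raw mask", {
  img <- fl_image(array(rep(c(200L, 50L, 40L), each = 6 * 8), dim = c(6, 8, 3)))
  cfg <- segmentation_config(mode = "rgb_red", min_component_area = 0,
                             morphology_radius = 0)
  expect_identical(sum(segment_plant(img, cfg)), 6L * 8L)
})

test_that("raising the red threshold never adds pixels (monotonicity)", {
  img <- fl_image(withr::with_seed(12, array(sample(0:255, 40 * 40 * 3, TRUE),
                                             dim = c(40, 40, 3))))
  prev <- NULL
  for (thr in c(60, 110, 160, 210)) {
    cfg <- segmentation_config(mode = "rgb_red", red_threshold = thr,
                               min_component_area = 0, morphology_radius = 0)
    m <- segment_plant(img, cfg)
    if (!is.null(prev)) expect_true(all(prev[m]))  # m subset of prev
    prev <- m
  }
})

test_that("remove_noise deletes small components and preserves solid shapes", {
  cfg <- segmentation_config(min_component_area = 5, morphology_radius = 0)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(remove_noise(empty, cfg), empty)

  lone <- empty
  lone[5, 5] <- TRUE
  expect_identical(sum(remove_noise(lone, cfg)), 0L)

  # one solid 20x20 square, radius-1 opening: brute-force morphology oracle
  sq <- matrix(FALSE, 30, 30)
  sq[6:25, 6:25] <- TRUE
  cfg1 <- segmentation_config(min_component_area = 5, morphology_radius = 1)
  expected <- brute_force_opening_3x3(sq)
  expect_identical(remove_noise(sq, cfg1), expected)
  expect_identical(sum(remove_noise(sq, cfg1)), 400L)
})

test_that("opening matches the brute-force oracle on random masks", {
  cfg <- segmentation_config(min_component_area = 0, morphology_radius = 1)
  for (s in 1:4) {
    m <- withr::with_seed(s, matrix(runif(22 * 22) < 0.45, 22, 22))
    expect_identical(remove_noise(m, cfg), brute_force_opening_3x3(m))
  }
})

test_that("remove_noise is idempotent when the opening radius is 0", {
  cfg <- segmentation_config(min_component_area = 7, morphology_radius = 0)
  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(runif(30 * 30) < 0.4, 30, 30))
    once <- remove_noise(m, cfg)
    expect_identical(remove_noise(once, cfg), once)
    expect_true(all(m[once]))  # output subset of input
  }
})

test_that("component filtering uses 8-connectivity", {
  # a diagonal chain of 6 pixels is one 8-connected component of size 6,
  # but six 4-connected singletons; with min area 5 it must survive
  m <- matrix(FALSE, 10, 10)
  for (k in 1:6) m[k + 1, k + 1] <- TRUE
  cfg <- segmentation_config(min_component_area = 5, morphology_radius = 0)
  expect_identical(remove_noise(m, cfg), m)
})

test_that("auto mode switches from HSV to the red rule as the plant grows", {
  big <- render_plant_image(scene_config(seed = 2))           # > switch area
  small <- render_plant_image(small_scene(seed = 2, scale = 0.5))
  cfg <- segmentation_config(mode = "auto")
  cfg_red <- segmentation_config(mode = "rgb_red")
  cfg_hsv <- segmentation_config(mode = "hsv")
  expect_identical(segment_plant(big$image, cfg), segment_plant(big$image, cfg_red))
  expect_identical(segment_plant(small$image, cfg), segment_plant(small$image, cfg_hsv))
})

test_that("segmentation recovers truth masks with high Jaccard", {
  for (s in c(1, 5, 9)) {
    sc <- render_plant_image(scene_config(stress_fraction = 0.2, seed = s))
    expect_gte(mask_jaccard(segment_plant(sc$image), sc$plant_mask), 0.95)
  }
})
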