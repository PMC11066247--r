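test_that("stratified split yields exact per-class counts and determinism", {
  gt <- tibble::tibble(r = runif(100, 0, 255), g = runif(100, 0, 255),
                       b = runif(100, 0, 255),
                       label = rep(c("non_stressed", "stressed"), each = 50))
  sp <- split_ground_truth(gt, c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(vapply(sp, length, integer(1)),
                   c(train = 60L, validation = 20L, test = 20L))
  for (part in sp) {
    expect_identical(sum(gt$label[part] == "stressed"), length(part) %/% 2L)
  }
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(sort(unname(unlist(sp))), 1:100)
  expect_identical(split_ground_truth(gt, c(0.6, 0.2, 0.2), seed = 3), sp)

  expect_error(split_ground_truth(gt, c(0.5, 0.5, 0)), class = "afpheno_validation_error")
  expect_error(split_ground_truth(gt, c(0.98, 0.01, 0.01)),
               class = "afpheno_validation_error")
})

test_that("point-mass classes are separated perfectly; tie selects ensemble", {
  gt <- point_mass_ground_truth(100)
  sp <- split_ground_truth(gt, seed = 1)
  b <- suppressWarnings(train_all(gt, sp, classifier_specs(seed = 2)))
  expect_true(all(b$report$test_accuracy == 1))
  expect_true(all(b$report$validation_accuracy == 1))
  expect_identical(b$selected_family, "ensemble_bagged_trees")
  expect_identical(nrow(b$report), 6L)
})

test_that("train_all rejects single-class training data", {
  gt <- gaussian_ground_truth(50, seed = 2)
  sp <- split_ground_truth(gt, seed = 1)
  gt$label <- "stressed"
  expect_error(train_all(gt, sp), class = "afpheno_validation_error")
})

test_that("the pruned decision tree never exceeds 20 splits", {
  # hard problem (permuted labels) would otherwise grow a huge tree
  gt <- gaussian_ground_truth(800, seed = 5)
  gt$label <- withr::with_seed(6, sample(gt$label))
  sp <- split_ground_truth(gt, seed = 7)
  b <- suppressWarnings(train_all(gt, sp, classifier_specs(families = "decision_tree")))
  tree <- b$models$decision_tree$model
  expect_lte(sum(tree$frame$var != "<leaf>"), 20)
})

test_that("naive Bayes predictions equal hand-computed Gaussian posteriors", {
  # <= 20 training rows, hand-computed posterior comparison
  gt <- gaussian_ground_truth(10, seed = 8)
  x <- as.data.frame(gt[, c("r", "g", "b")])
  y <- factor(gt$label, levels = c("non_stressed", "stressed"))
  fit <- afpheno:::fit_family("naive_bayes", x, y, seed = 1)

  newx <- as.data.frame(gaussian_ground_truth(25, seed = 9)[, c("r", "g", "b")])
  pred <- fit$predict(fit$model, newx)

  # independent oracle: per-channel Gaussian likelihoods x class priors
  oracle <- apply(newx, 1, function(v) {
    post <- vapply(levels(y), function(cl) {
      rows <- x[y == cl, ]
      prior <- mean(y == cl)
      lik <- prod(vapply(1:3, function(ch) {
        dnorm(v[ch], mean(rows[[ch]]), sd(rows[[ch]]))
      }, numeric(1)))
      prior * lik
    }, numeric(1))
    names(post)[which.max(post)]
  })
  expect_identical(as.character(pred), unname(oracle))
})

test_that("pipeline determinism: same seeds give identical bundles and masks", {
  gt <- gaussian_ground_truth(300, seed = 4)
  sp <- split_ground_truth(gt, seed = 5)
  b1 <- suppressWarnings(train_all(gt, sp, classifier_specs(seed = 6)))
  b2 <- suppressWarnings(train_all(gt, sp, classifier_specs(seed = 6)))
  expect_identical(b1$report, b2$report)

  sc <- render_plant_image(small_scene(stress_fraction = 0.3, seed = 10))
  mask <- segment_plant(sc$image)
  expect_identical(classify_image(sc$image, mask, b1),
                   classify_image(sc$image, mask, b2))
})

test_that("classify_image respects the plant mask and point-mass colours", {
  gt <- point_mass_ground_truth(100)
  sp <- split_ground_truth(gt, seed = 1)
  b <- suppressWarnings(train_all(gt, sp, classifier_specs(seed = 2)))

  empty <- matrix(FALSE, 8, 8)
  img <- fl_image(array(0L, dim = c(8, 8, 3)))
  expect_identical(sum(classify_image(img, empty, b)), 0L)

  # plant region entirely the stressed training colour
  img2 <- fl_image(array(rep(c(200L, 150L, 20L), each = 64), dim = c(8, 8, 3)))
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  sm <- classify_image(img2, mask, b)
  expect_identical(sm, mask)

  expect_error(classify_image(img2, mask, list()), class = "afpheno_state_error")
})

test_that("stress overlay recolours exactly the stressed pixels blue", {
  img <- fl_image(withr::with_seed(3, array(sample(0:254, 10 * 10 * 3, TRUE),
                                            dim = c(10, 10, 3))))
  sm <- matrix(FALSE, 10, 10)
  sm[cbind(c(2, 5, 9), c(3, 7, 1))] <- TRUE
  out <- render_stress_overlay(img, sm)
  diff_px <- which(apply(unclass(out) != unclass(img), c(1, 2), any))
  expect_identical(sort(diff_px), sort(which(sm)))
  expect_true(all(out[, , 1][sm] == 0 & out[, , 2][sm] == 0 & out[, , 3][sm] == 255))

  # empty mask leaves the image untouched
  expect_identical(unclass(render_stress_overlay(img, matrix(FALSE, 10, 10))),
                   unclass(img))
})

test_that("bundle persistence enforces the feature contract", {
  gt <- point_mass_ground_truth(50)
  sp <- split_ground_truth(gt, seed = 1)
  b <- suppressWarnings(train_all(gt, sp, classifier_specs(families = "naive_bayes")))
  f <- withr::local_tempfile(fileext = ".rds")
  save_bundle(b, f)
  b2 <- load_bundle(f)
  expect_identical(b2$report, b$report)
  expect_error(load_bundle(f, expected_contract = c("r", "g", "b", "nir")),
               class = "afpheno_contract_error")
})

test_that("tidy and glance summarise the bundle", {
  gt <- point_mass_ground_truth(60)
  sp <- split_ground_truth(gt, seed = 2)
  b <- suppressWarnings(train_all(gt, sp, classifier_specs(seed = 1)))
  td <- tidy(b)
  expect_identical(nrow(td), 6L)
  expect_identical(sum(td$selected), 1L)
  gl <- glance(b)
  expect_identical(gl$selected_family, b$selected_family)
  expect_identical(gl$n_rows, 120L)
  rep <- accuracy_report(b)
  expect_true(all(rep$test_accuracy >= 0 & rep$test_accuracy <= 100))
})
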