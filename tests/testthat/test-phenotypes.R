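test_that("percentage_stress is the exact pixel ratio", {
  plant <- matrix(FALSE, 20, 20); plant[1:20, 1:20] <- TRUE
  none <- matrix(FALSE, 20, 20)
  expect_identical(percentage_stress(none, plant), 0)
  expect_identical(percentage_stress(plant, plant), 100)

  plant2 <- matrix(FALSE, 10, 10); plant2[1:10, 1:10] <- TRUE
  sm <- matrix(FALSE, 10, 10); sm[1:5, 1:5] <- TRUE
  expect_identical(percentage_stress(sm, plant2), 25)

  expect_error(percentage_stress(none, none), class = "afpheno_undefined_value_error")
})

test_that("stressed pixels outside the plant mask are not counted", {
  plant <- matrix(FALSE, 6, 6); plant[2:4, 2:4] <- TRUE    # 9 pixels
  sm <- matrix(FALSE, 6, 6); sm[4:6, 4:6] <- TRUE          # 9, only 1 inside
  expect_equal(percentage_stress(sm, plant), 100 / 9)
})

test_that("moving average matches the brute-force trailing mean", {
  brute <- function(x, n) {
    vapply(seq_along(x), function(i) mean(x[max(1, i - n + 1):i]), numeric(1))
  }
  expect_identical(moving_average_percentage_stress(c(0, 10, 20), 3), c(0, 5, 10))
  expect_identical(moving_average_percentage_stress(c(7, 7, 7, 7), 2), c(7, 7, 7, 7))
  x <- c(3, 9, 1, 4)
  expect_identical(moving_average_percentage_stress(x, 1), x)
  for (s in 1:10) {
    v <- withr::with_seed(s, runif(sample(1:15, 1), 0, 100))
    for (n in c(1, 2, 3, 7)) {
      expect_equal(moving_average_percentage_stress(v, n), brute(v, n))
    }
  }
  expect_error(moving_average_percentage_stress(1:3, 0), class = "afpheno_validation_error")
})

test_that("smoothing never increases variance for n >= 2", {
  for (s in 1:8) {
    v <- withr::with_seed(s, runif(20, 0, 100))
    for (n in c(2, 3, 5)) {
      expect_lte(var(moving_average_percentage_stress(v, n)), var(v) + 1e-12)
    }
  }
})

test_that("genotype averages use the closed-form mean and standard error", {
  series <- tibble::tibble(
    plant_id = c("a", "b", "c", "d"), genotype = "G", dag = 20L,
    percentage_stress = c(10, 20, 30, 42), segmentation_empty = FALSE)
  s3 <- genotype_average(series[1:3, ])
  expect_equal(s3$mean, 20)
  expect_equal(s3$stderr, 10 / sqrt(3))
  expect_identical(s3$n_replicates, 3L)

  one <- genotype_average(series[4, ])
  expect_equal(one$mean, 42)
  expect_equal(one$stderr, 0)
  expect_identical(one$n_replicates, 1L)

  same <- tibble::tibble(plant_id = letters[1:4], genotype = "G", dag = 1L,
                         percentage_stress = 15, segmentation_empty = FALSE)
  expect_equal(genotype_average(same)$stderr, 0)

  expect_error(genotype_average(series, genotype = "H"),
               class = "afpheno_missing_data_error")
})

test_that("compare_genotypes implements the Welch test", {
  mk <- function(g, vals) tibble::tibble(
    plant_id = paste0(g, seq_along(vals)), genotype = g, dag = 9L,
    percentage_stress = vals, segmentation_empty = FALSE)

  # identical replicate sets: difference 0, p = 1
  same <- dplyr::bind_rows(mk("A", c(5, 7, 9)), mk("B", c(5, 7, 9)))
  r <- compare_genotypes(same, "A", "B", dag = 9)
  expect_equal(r$mean_diff, 0)
  expect_equal(r$p_value, 1)

  # well-separated groups with tiny jitter: p < 0.001
  jit <- withr::with_seed(2, rnorm(6, 0, 0.01))
  far <- dplyr::bind_rows(mk("A", 0 + jit), mk("B", 30 + jit))
  expect_lt(compare_genotypes(far, "A", "B", dag = 9)$p_value, 0.001)

  # closed-form Welch t and Satterthwaite df
  a <- c(10, 20); b <- c(13, 19)
  two <- dplyr::bind_rows(mk("A", a), mk("B", b))
  got <- compare_genotypes(two, "A", "B", dag = 9)
  se2 <- var(a) / 2 + var(b) / 2
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 2)^2 / 1 + (var(b) / 2)^2 / 1)
  expect_equal(got$mean_diff, mean(a) - mean(b))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), df))

  expect_error(compare_genotypes(mk("A", c(1, 2)), "A", "B", dag = 9),
               class = "afpheno_insufficient_data_error")
})

test_that("flagged empty-segmentation records are excluded from summaries", {
  series <- tibble::tibble(
    plant_id = c("a", "b", "c"), genotype = "G", dag = 12L,
    percentage_stress = c(10, 20, NA), segmentation_empty = c(FALSE, FALSE, TRUE))
  s <- genotype_average(series)
  expect_identical(s$n_replicates, 2L)
  expect_equal(s$mean, 15)
})

test_that("phenotype report export is complete and byte-deterministic", {
  exp <- tiny_experiment()
  res <- tiny_pipeline()
  pheno <- res$phenotypes
  expect_s3_class(pheno, "stress_phenotypes")
  expect_identical(nrow(pheno), nrow(exp$dataset$manifest))
  expect_true(all(pheno$percentage_stress >= 0 & pheno$percentage_stress <= 100,
                  na.rm = TRUE))
  expect_true(all(pheno$moving_average >= 0 & pheno$moving_average <= 100,
                  na.rm = TRUE))
  # conservation: stressed <= plant pixels
  expect_true(all(pheno$stressed_pixels <= pheno$plant_pixels))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_phenotype_report(pheno, d1)
  export_phenotype_report(pheno, d2)
  for (f in c("phenotypes.csv", "genotype_summary.csv", "comparisons.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # genotype summary has one row per (genotype, day) present
  summ <- readr::read_csv(file.path(d1, "genotype_summary.csv"), show_col_types = FALSE)
  expect_identical(nrow(summ),
                   nrow(dplyr::distinct(drop_na_pheno(pheno), genotype, dag)))

  expect_error(export_phenotype_report(pheno[0, ], d1), class = "afpheno_validation_error")
})

test_that("autoplot returns ggplot objects", {
  res <- tiny_pipeline()
  expect_s3_class(autoplot(res$phenotypes), "ggplot")
  expect_s3_class(autoplot(res$phenotypes, moving_average = TRUE), "ggplot")
  expect_s3_class(autoplot(res$bundle), "ggplot")
})
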