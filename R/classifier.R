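# Stress-detection classifier: six model families trained on the ground-truth
# pixel table, compared on held-out validation and test rows, the best one (by
# test accuracy) used to map every plant pixel of an image to {0 =
# non-stressed, 1 = stressed}.

family_order <- c("ensemble_bagged_trees", "neural_network", "svm_quadratic",
                  "decision_tree", "logistic_regression", "naive_bayes")

#' The six classifier family specifications
#'
#' Fixed per-family hyperparameters: bagged-trees ensemble of 30 bootstrap
#' trees (all 3 features eligible at every split, i.e. pure bagging); a
#' single-hidden-layer neural network of 25 units; an SVM with a quadratic
#' (degree-2 polynomial) kernel and features standardised on training
#' statistics; a decision tree pruned to at most 20 splits; logistic
#' regression; and Gaussian naive Bayes.
#'
#' @param families Subset of families to train, in the canonical order (the
#'   order also breaks selection ties).
#' @param seed Base seed; each family trains under its own derived seed.
#' @return Tibble with columns `family`, `seed`.
#' @export
classifier_specs <- function(families = family_order, seed = 1) {
  bad <- setdiff(families, family_order)
  if (length(bad) > 0) {
    stop_afpheno(paste0("unknown classifier family: ", paste(bad, collapse = ", ")),
                 "validation_error")
  }
  families <- family_order[family_order %in% families]
  tibble::tibble(family = families,
                 seed = vapply(seq_along(families),
                               function(i) derive_seed(seed, i), integer(1)))
}

#' Stratified train/validation/test split of a ground-truth table
#'
#' Rows are split per class so the class balance is preserved in every part;
#' deterministic given the seed.
#'
#' @param table Ground-truth tibble with a `label` column.
#' @param fractions Length-3 positive fractions `(train, validation, test)`
#'   summing to 1.
#' @param seed Integer RNG seed.
#' @return Named list of disjoint integer row-index vectors `train`,
#'   `validation`, `test` whose union is all rows.
#' @export
split_ground_truth <- function(table, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop_afpheno("fractions must be 3 positive numbers summing to 1", "validation_error")
  }
  lab <- as.character(table$label)
  if (!all(pixel_classes() %in% lab)) {
    stop_afpheno("both classes must be present before splitting", "validation_error")
  }
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in pixel_classes()) {
      idx <- sample(which(lab == cl))
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      n_te <- n - n_tr - n_va
      if (n_tr < 1 || n_va < 1 || n_te < 1) {
        stop_afpheno(paste0("split leaves zero '", cl, "' rows in one part"),
                     "validation_error")
      }
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$validation <- c(parts$validation, idx[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, idx[n_tr + n_va + seq_len(n_te)])
    }
  })
  lapply(parts, sort)
}

# --- family fitting -------------------------------------------------------
# Each fitter returns list(model, predict = function(model, x) factor labels)
# where x is a data frame with columns r, g, b.

fit_family <- function(family, x, y, seed) {
  y <- as_class_factor(y)
  switch(family,
    ensemble_bagged_trees = {
      model <- with_seed(seed, randomForest::randomForest(
        x = x, y = y, ntree = 30, mtry = ncol(x), replace = TRUE))
      list(model = model,
           predict = function(model, newx) {
             # majority vote with a fixed tie rule (15-15 -> non_stressed);
             # randomForest's own tie-breaking consults the global RNG
             p <- predict(model, newx, type = "vote", norm.votes = TRUE)
             as_class_factor(ifelse(p[, "stressed"] > 0.5, "stressed", "non_stressed"))
           })
    },
    neural_network = {
      ctr <- vapply(x, mean, numeric(1))
      scl <- vapply(x, sd, numeric(1))
      scl[scl == 0 | is.na(scl)] <- 1
      xs <- sweep(sweep(as.matrix(x), 2, ctr), 2, scl, "/")
      model <- with_seed(seed, nnet::nnet(
        xs, stats::model.matrix(~ y - 1)[, 2, drop = FALSE], size = 25,
        maxit = 300, decay = 1e-4, entropy = TRUE, trace = FALSE, MaxNWts = 5000))
      list(model = list(net = model, center = ctr, scale = scl),
           predict = function(model, newx) {
             xs <- sweep(sweep(as.matrix(newx), 2, model$center), 2, model$scale, "/")
             p <- predict(model$net, xs)
             as_class_factor(ifelse(p[, 1] > 0.5, "stressed", "non_stressed"))
           })
    },
    svm_quadratic = {
      model <- with_seed(seed, suppressWarnings(e1071::svm(
        x = as.matrix(x), y = y, kernel = "polynomial", degree = 2, coef0 = 1,
        cost = 1, scale = TRUE)))
      list(model = model,
           predict = function(model, newx) predict(model, as.matrix(newx)))
    },
    decision_tree = {
      df <- cbind(x, .label = y)
      model <- with_seed(seed, rpart::rpart(
        .label ~ ., data = df, method = "class",
        control = rpart::rpart.control(cp = 0, xval = 0, minsplit = 4)))
      # cap at 20 splits: prune back to the largest subtree within the cap
      cp_tab <- model$cptable
      ok <- cp_tab[cp_tab[, "nsplit"] <= 20, , drop = FALSE]
      cp_sel <- ok[nrow(ok), "CP"]
      model <- rpart::prune(model, cp = cp_sel)
      list(model = model,
           predict = function(model, newx) {
             as_class_factor(predict(model, newx, type = "class"))
           })
    },
    logistic_regression = {
      df <- cbind(x, .y = as.integer(y == "stressed"))
      model <- withCallingHandlers(
        glm(.y ~ r + g + b, data = df, family = binomial()),
        warning = function(w) {
          warn(paste0("logistic_regression: ", conditionMessage(w),
                      " (model retained)"))
          invokeRestart("muffleWarning")
        })
      list(model = model,
           predict = function(model, newx) {
             p <- predict(model, newx, type = "response")
             as_class_factor(ifelse(p > 0.5, "stressed", "non_stressed"))
           })
    },
    naive_bayes = {
      model <- e1071::naiveBayes(x = x, y = y)
      list(model = model,
           predict = function(model, newx) {
             # threshold = 0 keeps densities exact (no clamping), so predictions
             # equal the Gaussian posterior argmax
             predict(model, newx, threshold = 0, eps = 0)
           })
    },
    stop_afpheno(paste0("unknown classifier family: ", family), "validation_error")
  )
}

#' Train and compare all classifier families
#'
#' Fits every family on the training rows, scores accuracy (fraction of
#' correctly labelled rows) on the validation and test rows, and selects the
#' best family: maximum test accuracy, ties broken by validation accuracy,
#' then by the canonical family order.
#'
#' @param table Ground-truth tibble with columns `r, g, b, label`.
#' @param split Output of [split_ground_truth()].
#' @param specs Tibble from [classifier_specs()].
#' @return A `stress_classifier_bundle`: fitted models, the accuracy report
#'   (one row per family), the selected family and the split sizes. Use
#'   [tidy()] for the report and [predict()] / [classify_image()] to apply it.
#' @export
train_all <- function(table, split, specs = classifier_specs()) {
  x <- as.data.frame(table[, c("r", "g", "b")])
  y <- as_class_factor(table$label)
  if (length(unique(y[split$train])) < 2) {
    stop_afpheno("training rows contain a single class", "validation_error")
  }
  fits <- purrr::pmap(specs, function(family, seed) {
    fit <- fit_family(family, x[split$train, , drop = FALSE], y[split$train], seed)
    acc <- function(rows) {
      mean(fit$predict(fit$model, x[rows, , drop = FALSE]) == y[rows])
    }
    list(family = family, fit = fit,
         validation_accuracy = acc(split$validation),
         test_accuracy = acc(split$test))
  })
  report <- dplyr::bind_rows(purrr::map(fits, function(f) {
    tibble::tibble(family = f$family,
                   validation_accuracy = f$validation_accuracy,
                   test_accuracy = f$test_accuracy)
  }))
  ord <- order(-report$test_accuracy, -report$validation_accuracy,
               match(report$family, family_order))
  selected <- report$family[ord[1]]
  structure(list(
    models = stats::setNames(purrr::map(fits, "fit"), report$family),
    report = report,
    selected_family = selected,
    split_sizes = vapply(split, length, integer(1)),
    feature_contract = c("r", "g", "b"),
    n_rows = nrow(table)
  ), class = "stress_classifier_bundle")
}

#' @export
print.stress_classifier_bundle <- function(x, ...) {
  cat("<stress_classifier_bundle>\n")
  cat(sprintf("  %d families trained on %d / validated on %d / tested on %d pixel rows\n",
              nrow(x$report), x$split_sizes[["train"]],
              x$split_sizes[["validation"]], x$split_sizes[["test"]]))
  cat(sprintf("  selected: %s (test accuracy %.2f%%)\n", x$selected_family,
              100 * x$report$test_accuracy[x$report$family == x$selected_family]))
  invisible(x)
}

#' Predict pixel classes with a trained bundle
#'
#' @param object A `stress_classifier_bundle`.
#' @param newdata Data frame or matrix with columns `r, g, b` (0-255).
#' @param family Family to use; defaults to the selected one.
#' @param ... Unused.
#' @return Factor of `"non_stressed"` / `"stressed"`.
#' @export
predict.stress_classifier_bundle <- function(object, newdata,
                                             family = object$selected_family, ...) {
  if (!family %in% names(object$models)) {
    stop_afpheno(paste0("family '", family, "' not in bundle"), "state_error")
  }
  newdata <- as.data.frame(newdata)
  names(newdata) <- object$feature_contract
  fit <- object$models[[family]]
  fit$predict(fit$model, newdata)
}

#' @rdname tidy
#' @details `tidy()` on a `stress_classifier_bundle` returns the per-family
#'   accuracy report; `glance()` a one-row summary with the selected family.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy stress_classifier_bundle
#' @export
tidy.stress_classifier_bundle <- function(x, ...) {
  dplyr::mutate(x$report, selected = .data$family == x$selected_family)
}

#' @rdname tidy
#' @method glance stress_classifier_bundle
#' @export
glance.stress_classifier_bundle <- function(x, ...) {
  sel <- x$report[x$report$family == x$selected_family, ]
  tibble::tibble(selected_family = x$selected_family,
                 validation_accuracy = sel$validation_accuracy,
                 test_accuracy = sel$test_accuracy,
                 n_rows = x$n_rows,
                 n_train = x$split_sizes[["train"]],
                 n_validation = x$split_sizes[["validation"]],
                 n_test = x$split_sizes[["test"]])
}

#' Accuracy report in percent
#'
#' The comparison table as it is exported: one row per family, validation and
#' test accuracy in percent rounded to 2 decimals.
#'
#' @param bundle A `stress_classifier_bundle`.
#' @return Tibble `family, validation_accuracy, test_accuracy`.
#' @export
accuracy_report <- function(bundle) {
  stopifnot(inherits(bundle, "stress_classifier_bundle"))
  tibble::tibble(
    family = bundle$report$family,
    validation_accuracy = round(100 * bundle$report$validation_accuracy, 2),
    test_accuracy = round(100 * bundle$report$test_accuracy, 2)
  )
}

#' Classify every plant pixel of an image
#'
#' Applies the bundle's selected model to the (r, g, b) triple of each pixel
#' inside the plant mask. Pixels outside the mask are never classified: the
#' stress mask is FALSE there by construction.
#'
#' @param image An [fl_image()].
#' @param mask Logical plant mask of matching size.
#' @param bundle A trained `stress_classifier_bundle`.
#' @param family Optional family override.
#' @return Logical stress mask (TRUE = stressed), a subset of `mask`.
#' @export
classify_image <- function(image, mask, bundle, family = bundle$selected_family) {
  if (!inherits(bundle, "stress_classifier_bundle")) {
    stop_afpheno("`bundle` is not a trained classifier bundle", "state_error")
  }
  stopifnot(is_fl_image(image), identical(dim(image)[1:2], dim(mask)))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  feats <- data.frame(r = as.numeric(image[, , 1][idx]),
                      g = as.numeric(image[, , 2][idx]),
                      b = as.numeric(image[, , 3][idx]))
  pred <- predict(bundle, feats, family = family)
  out[idx] <- pred == "stressed"
  out
}

#' Recolour predicted stressed pixels blue
#'
#' Stressed pixels are set to (0, 0, 255); all other pixels — non-stressed
#' plant tissue and background — keep their original colour.
#'
#' @param image An [fl_image()].
#' @param stress_mask Logical stress mask of matching size.
#' @return An [fl_image()].
#' @export
render_stress_overlay <- function(image, stress_mask) {
  stopifnot(is_fl_image(image), identical(dim(image)[1:2], dim(stress_mask)))
  px <- unclass(image)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  r[stress_mask] <- 0L
  g[stress_mask] <- 0L
  b[stress_mask] <- 255L
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  fl_image(px)
}

bundle_format_version <- 1L

#' Persist / restore a trained classifier bundle
#'
#' The serialised file embeds a format version and the feature contract
#' (`r, g, b`); loading a bundle whose contract does not match the expectation
#' is an error.
#'
#' @param bundle A `stress_classifier_bundle`.
#' @param path File path (RDS).
#' @param expected_contract Feature columns the caller will supply.
#' @return `save_bundle`: the path invisibly; `load_bundle`: the bundle.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "stress_classifier_bundle"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(version = bundle_format_version,
               contract = bundle$feature_contract, bundle = bundle), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path, expected_contract = c("r", "g", "b")) {
  if (!file.exists(path)) stop_afpheno(paste0("bundle not found: ", path), "not_found_error")
  obj <- readRDS(path)
  if (!identical(obj$version, bundle_format_version)) {
    stop_afpheno("bundle was written by an incompatible version", "contract_error")
  }
  if (!identical(obj$contract, expected_contract)) {
    stop_afpheno(paste0("bundle feature contract (", paste(obj$contract, collapse = ","),
                        ") does not match expected (",
                        paste(expected_contract, collapse = ","), ")"),
                 "contract_error")
  }
  obj$bundle
}
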