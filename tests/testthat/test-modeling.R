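separable_toy <- function(n = 100L, seed = 1L) {
  set.seed(seed)
  x <- cbind(sep = c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3)),
             noise = rnorm(n))
  y <- rep(c("negative", "positive"), each = n / 2)
  o <- sample(n)
  list(features = x[o, ], labels = y[o])
}

test_that("compute_metrics matches the direct formulas", {
  m <- compute_metrics(tp = 9, fn = 1, tn = 8, fp = 2)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["f1"]), 18 / 21)

  perfect <- compute_metrics(10, 0, 10, 0)
  expect_equal(unname(perfect), rep(1, 4L))

  expect_warning(z <- compute_metrics(0, 2, 8, 0), "sensitivity")
  expect_equal(unname(z["sensitivity"]), 0)
  expect_error(compute_metrics(0, 0, 0, 0))
})

test_that("accuracy lies between sensitivity and specificity for balanced classes", {
  set.seed(2)
  for (trial in 1:50) {
    pos <- sample(5:50, 1L)
    tp <- sample(0:pos, 1L)
    tn <- sample(0:pos, 1L)
    m <- suppressWarnings(compute_metrics(tp, pos - tn, tn, pos - tp))
    expect_gte(m[["accuracy"]], min(m[["sensitivity"]], m[["specificity"]]))
    expect_lte(m[["accuracy"]], max(m[["sensitivity"]], m[["specificity"]]))
  }
})

test_that("model grids carry the documented cardinalities", {
  expect_length(grid_points(model_grid("knn")), 9L)
  expect_length(grid_points(model_grid("rf")), 9L)
  expect_length(grid_points(model_grid("svm")), 63L)   # 7 penalties x 9 widths
  expect_length(grid_points(model_grid("ann")), 75L)   # 5 x 5 x 3
  ref <- model_grid("ann", "refinement")
  expect_equal(ref$parameters$n_neurons, 7:10)
  expect_length(grid_points(ref), 60L)                 # 4 x 5 x 3
})

test_that("cross_validate: separable data is learned by all four methods", {
  toy <- separable_toy()
  params <- list(
    knn = list(k = 3L),
    rf  = list(n_trees = 50L, leaf_size = 2L),
    svm = list(penalty = 1, kernel_width = 1),
    ann = list(n_neurons = 4L, epochs = 100L, momentum = 0.1,
               learning_rate = 0.5))
  for (m in names(params)) {
    r <- cross_validate(toy$features, toy$labels, m, params[[m]],
                        folds = 10L, seed = 1L)
    expect_equal(r$mean_metrics[["accuracy"]], 1.0,
                 tolerance = 0.02, label = paste("accuracy of", m))
  }
})

test_that("cross_validate: permuted labels sit at chance; reports are deterministic", {
  toy <- separable_toy(seed = 3L)
  set.seed(4)
  yp <- sample(toy$labels)
  r <- cross_validate(toy$features, yp, "knn", list(k = 3L), seed = 1L)
  expect_lt(abs(r$mean_metrics[["accuracy"]] - 0.5), 0.1)

  for (m in c("knn", "rf", "ann")) {
    p <- if (m == "ann") list(n_neurons = 3L, epochs = 20L,
                              learning_rate = 0.5) else list(k = 3L,
                              n_trees = 20L, leaf_size = 2L)
    r1 <- cross_validate(toy$features, toy$labels, m, p, seed = 5L)
    r2 <- cross_validate(toy$features, toy$labels, m, p, seed = 5L)
    expect_identical(r1$fold_metrics, r2$fold_metrics, label = m)
  }

  expect_error(cross_validate(toy$features[1:5, ], toy$labels[1:5],
                              "knn", folds = 10L), "fewer rows")
})

test_that("fold assignment partitions rows; groups stay within one fold", {
  labels <- rep(c("a", "b"), each = 50L)
  groups <- rep(1:20, each = 5L)
  f <- phagehost:::assign_folds(labels, 5L, seed = 1L, groups = groups)
  expect_true(all(f %in% 1:5))
  expect_true(all(vapply(split(f, groups), function(x)
    length(unique(x)) == 1L, logical(1L))))
  f2 <- phagehost:::assign_folds(labels, 10L, seed = 1L)
  expect_equal(length(f2), 100L)
  expect_true(all(table(f2) == 10L))
})

test_that("standardization derives from training rows only", {
  x <- rbind(matrix(0, 10, 2), matrix(100, 10, 2))
  st <- phagehost:::standardize_fit(x[1:10, ])
  expect_equal(st$mu, c(0, 0))
  expect_equal(st$sd, c(1, 1))           # sd 0 -> 1, no test leakage
  z <- phagehost:::standardize_apply(x[11:20, ], st)
  expect_equal(unique(as.vector(z)), 100)
})

test_that("explore covers the product and sorts reports; refine is ANN-only", {
  toy <- separable_toy(n = 60L)
  datasets <- list(d1 = toy, d2 = toy)
  grids <- list(model_grid("knn"))
  reports <- explore(datasets, grids, folds = 5L, seed = 1L)
  expect_length(reports, 18L)
  expect_equal(vapply(reports, `[[`, character(1L), "dataset_name"),
               rep(c("d1", "d2"), each = 9L))
  expect_equal(vapply(reports[1:9], function(r) r$params$k, integer(1L)), 1:9)
  expect_length(explore(datasets, list(), folds = 5L), 0L)

  small_ann <- structure(list(method = "ann",
                              parameters = list(n_neurons = 7:8,
                                                epochs = 10L,
                                                momentum = 0.1,
                                                learning_rate = 0.5)),
                         class = "model_grid")
  ref <- refine(list(d1 = toy), small_ann, folds = 5L, seed = 1L)
  expect_length(ref, 2L)
  expect_true(all(vapply(ref, `[[`, character(1L), "method") == "ann"))
})

test_that("select_best keys on F1 then accuracy then model size", {
  mk <- function(f1, acc, k) {
    structure(list(dataset_name = "d", method = "knn", params = list(k = k),
                   mean_metrics = c(accuracy = acc, f1 = f1,
                                    sensitivity = 0, specificity = 0),
                   split = "validation"), class = "eval_report")
  }
  best <- select_best(list(mk(0.8, 0.9, 3L), mk(0.9, 0.7, 5L),
                           mk(0.9, 0.7, 7L)))
  # ties on f1/accuracy resolve to the larger k (smaller model)
  expect_equal(best$params$k, 7L)
})

test_that("final_evaluate averages the 10 fold-models on the test set", {
  toy <- separable_toy(n = 120L, seed = 6L)
  train <- list(features = toy$features[1:100, ], labels = toy$labels[1:100])
  test <- list(features = toy$features[101:120, ], labels = toy$labels[101:120])
  r <- final_evaluate("knn", list(k = 3L), train, test, folds = 10L,
                      seed = 1L)
  expect_equal(r$split, "test")
  expect_equal(nrow(r$fold_metrics), 10L)
  expect_gt(r$mean_metrics[["accuracy"]], 0.95)
  expect_error(final_evaluate("knn", list(k = 3L), train,
                              list(features = test$features[, 1L,
                                                            drop = FALSE],
                                   labels = test$labels)),
               "mismatch")
})

test_that("result matrix exports, warns on gaps, errors on duplicates", {
  toy <- separable_toy(n = 60L)
  reports <- explore(list(d1 = toy, d2 = toy),
                     list(structure(list(method = "knn",
                                         parameters = list(k = c(1L, 3L, 5L))),
                                    class = "model_grid")),
                     folds = 5L, seed = 1L)
  f <- withr::local_tempfile(fileext = ".csv")
  m <- export_result_matrix(reports, "f1", f)
  expect_equal(dim(m), c(2L, 3L))
  back <- read_result_matrix(f)
  expect_equal(unname(back), unname(m))

  expect_warning(export_result_matrix(reports[-1L], "f1",
                                      withr::local_tempfile(fileext = ".csv")),
                 "empty cells")
  expect_error(export_result_matrix(c(reports, reports[1L]), "f1",
                                    withr::local_tempfile(fileext = ".csv")),
               "duplicate")
})
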