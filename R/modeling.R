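#' Binary classification metrics from a confusion matrix
#'
#' accuracy = (tp+tn)/total; sensitivity = tp/(tp+fn); specificity =
#' tn/(tn+fp); f1 = 2tp/(2tp+fp+fn). A zero denominator yields 0 with a
#' warning.
#'
#' @param tp,fp,tn,fn Confusion counts (non-negative; total > 0).
#' @return Named numeric vector `accuracy`, `f1`, `sensitivity`,
#'   `specificity`.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, " (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  c(accuracy = (tp + tn) / total,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn, "f1"),
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"))
}

metrics_from_labels <- function(truth, predicted, positive = "positive") {
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  fn <- sum(truth == positive & predicted != positive)
  compute_metrics(tp, fp, tn, fn)
}

#' Hyperparameter grids for the four classifier families
#'
#' Exploration-phase grids: k-NN K in 1..9; RF with 10^2..10^4 trees and
#' minimum leaf sizes 2..4; RBF-SVM with penalty 10^-2..10^4 and kernel
#' width 10^-4..10^4; ANN with 2..6 hidden neurons, 10..100 epochs and
#' momentum 0.1/0.4/0.7 at learning rate 1e-4. `phase = "refinement"`
#' swaps the ANN neuron list for 7..10.
#'
#' @param method Classifier family.
#' @param phase `"exploration"` or `"refinement"` (ANN only differs).
#' @return A `model_grid`: list with `method` and `parameters` (named
#'   lists of candidate values).
#' @export
model_grid <- function(method = c("knn", "rf", "svm", "ann"),
                       phase = c("exploration", "refinement")) {
  method <- match.arg(method)
  phase <- match.arg(phase)
  parameters <- switch(method,
    knn = list(k = 1:9),
    rf  = list(n_trees = c(1e2, 1e3, 1e4), leaf_size = 2:4),
    svm = list(penalty = 10^(-2:4), kernel_width = 10^(-4:4)),
    ann = list(n_neurons = if (phase == "exploration") 2:6 else 7:10,
               epochs = c(10, 25, 50, 75, 100),
               momentum = c(0.1, 0.4, 0.7),
               learning_rate = 1e-4))
  structure(list(method = method, parameters = parameters),
            class = "model_grid")
}

#' Enumerate the points of a model grid
#' @param grid A [model_grid()].
#' @return List of named parameter lists, in grid order (first parameter
#'   varies slowest).
#' @export
grid_points <- function(grid) {
  df <- rev(expand.grid(rev(grid$parameters), KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

param_string <- function(params) {
  paste(names(params), vapply(params, format, character(1L)),
        sep = "=", collapse = ",")
}

# stratified fold assignment; with `groups`, all rows of a group land in
# the same fold (group-aware folding defeats replicate leakage)
assign_folds <- function(labels, folds, seed, groups = NULL) {
  set.seed(seed)
  fold <- integer(length(labels))
  if (is.null(groups)) {
    for (lv in unique(labels)) {
      rows <- which(labels == lv)
      fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  } else {
    for (lv in unique(labels)) {
      rows <- which(labels == lv)
      gs <- split(rows, groups[rows])
      gf <- sample(rep_len(seq_len(folds), length(gs)))
      for (i in seq_along(gs)) fold[gs[[i]]] <- gf[i]
    }
  }
  fold
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2L, st$mu, "-"), 2L, st$sd, "/")
}

#' k-fold cross-validation of one classifier configuration
#'
#' Stratified seeded fold assignment; features are standardized per fold
#' using training-fold statistics only (no leakage from the validation
#' fold). With `groups` set (e.g. the distinct pair id), all replicates
#' of a group are confined to one fold — the corrective, group-aware
#' protocol; the default reproduces plain row-level folding.
#'
#' @param features Numeric matrix.
#' @param labels Two-class label vector.
#' @param method,params Classifier family and hyperparameters
#'   (see [fit_classifier()]).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (folds and model fits).
#' @param groups Optional grouping vector for group-aware folding.
#' @param dataset_name Carried into the report.
#' @return An `eval_report`: `dataset_name`, `method`, `params`,
#'   `fold_metrics` (data.frame, one row per fold), `mean_metrics`,
#'   `split = "validation"`.
#' @export
cross_validate <- function(features, labels, method, params = list(),
                           folds = 10L, seed = 1L, groups = NULL,
                           dataset_name = "dataset") {
  features <- as.matrix(features)
  if (folds < 2L) stop("folds must be >= 2")
  if (nrow(features) < folds) stop("fewer rows than folds")
  if (length(unique(labels)) != 2L) stop("need both labels in the matrix")
  fold <- assign_folds(labels, folds, seed, groups)
  fm <- matrix(NA_real_, folds, 4L,
               dimnames = list(NULL, c("accuracy", "f1", "sensitivity",
                                       "specificity")))
  for (f in seq_len(folds)) {
    tr <- fold != f; va <- fold == f
    if (!any(va) || length(unique(labels[tr])) < 2L) next
    st <- standardize_fit(features[tr, , drop = FALSE])
    xtr <- standardize_apply(features[tr, , drop = FALSE], st)
    xva <- standardize_apply(features[va, , drop = FALSE], st)
    model <- fit_classifier(xtr, labels[tr], method, params,
                            seed = seed + f)
    pred <- predict_classifier(model, xva)
    fm[f, ] <- metrics_from_labels(labels[va], pred)
  }
  fm <- fm[stats::complete.cases(fm), , drop = FALSE]
  structure(list(dataset_name = dataset_name, method = method,
                 params = params,
                 fold_metrics = as.data.frame(fm),
                 mean_metrics = colMeans(fm),
                 split = "validation"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s | %s | %s | %s\n  acc %.3f  f1 %.3f  sens %.3f  spec %.3f\n",
              x$dataset_name, x$method, param_string(x$params), x$split,
              x$mean_metrics[["accuracy"]], x$mean_metrics[["f1"]],
              x$mean_metrics[["sensitivity"]],
              x$mean_metrics[["specificity"]]))
  invisible(x)
}

#' Exploration phase: full grid search over datasets and methods
#'
#' Cross-validates the Cartesian product datasets x methods x grid
#' points. Reports come back sorted by (dataset, method, parameters in
#' grid order).
#'
#' @param datasets Named list; each element a list with `features`,
#'   `labels`.
#' @param grids List of [model_grid()]s.
#' @param folds,seed As in [cross_validate()].
#' @return List of `eval_report`s.
#' @export
explore <- function(datasets, grids, folds = 10L, seed = 1L) {
  if (length(grids) == 0L) return(list())
  out <- list()
  for (ds in names(datasets)) {
    for (g in grids) {
      for (pt in grid_points(g)) {
        out[[length(out) + 1L]] <- cross_validate(
          datasets[[ds]]$features, datasets[[ds]]$labels,
          method = g$method, params = pt, folds = folds, seed = seed,
          dataset_name = ds)
      }
    }
  }
  out
}

#' Refinement phase: extended ANN neuron search on selected datasets
#'
#' As [explore()], restricted to the ANN family with hidden-layer sizes
#' 7..10 on the datasets that survived the exploratory phase (by default
#' the fixed-size 1e-6 set, NBN50, NB50 and CH).
#'
#' @param datasets Named list of selected feature sets.
#' @param ann_grid A [model_grid()] (default the ANN refinement grid).
#' @param folds,seed As in [cross_validate()].
#' @return List of `eval_report`s.
#' @export
refine <- function(datasets, ann_grid = model_grid("ann", "refinement"),
                   folds = 10L, seed = 1L) {
  explore(datasets, list(ann_grid), folds = folds, seed = seed)
}

#' Select the best configuration from a set of reports
#'
#' Key: mean validation F1; ties broken by accuracy, then by the smaller
#' model (fewer neurons or trees, larger k).
#'
#' @param reports List of `eval_report`s.
#' @return The winning `eval_report`.
#' @export
select_best <- function(reports) {
  stopifnot(length(reports) > 0L)
  size_of <- function(r) {
    p <- r$params
    (p$n_neurons %||% 0) + (p$n_trees %||% 0) - (p$k %||% 0)
  }
  key <- vapply(reports, function(r)
    c(r$mean_metrics[["f1"]], r$mean_metrics[["accuracy"]], -size_of(r)),
    numeric(3L))
  best <- order(key[1L, ], key[2L, ], key[3L, ], decreasing = TRUE)[1L]
  reports[[best]]
}

#' Held-out test evaluation of one configuration
#'
#' Re-runs 10-fold cross-validation on the training matrix to obtain the
#' 10 fold-models, standardizes the test matrix with each fold's training
#' statistics, and reports the mean over the 10 models' test-set metrics.
#'
#' @param method,params Winning configuration.
#' @param train,test Lists with `features` and `labels`; the test matrix
#'   must have been featurized with the training manifest's constants.
#' @param folds,seed As in [cross_validate()].
#' @param dataset_name Carried into the report.
#' @return An `eval_report` with `split = "test"`.
#' @export
final_evaluate <- function(method, params, train, test, folds = 10L,
                           seed = 1L, dataset_name = "dataset") {
  xtr_all <- as.matrix(train$features)
  xte_all <- as.matrix(test$features)
  if (ncol(xtr_all) != ncol(xte_all)) {
    stop("feature-length mismatch between train (", ncol(xtr_all),
         ") and test (", ncol(xte_all), ")")
  }
  fold <- assign_folds(train$labels, folds, seed)
  fm <- matrix(NA_real_, folds, 4L,
               dimnames = list(NULL, c("accuracy", "f1", "sensitivity",
                                       "specificity")))
  for (f in seq_len(folds)) {
    tr <- fold != f
    st <- standardize_fit(xtr_all[tr, , drop = FALSE])
    model <- fit_classifier(standardize_apply(xtr_all[tr, , drop = FALSE], st),
                            train$labels[tr], method, params, seed = seed + f)
    pred <- predict_classifier(model, standardize_apply(xte_all, st))
    fm[f, ] <- metrics_from_labels(test$labels, pred)
  }
  structure(list(dataset_name = dataset_name, method = method,
                 params = params, fold_metrics = as.data.frame(fm),
                 mean_metrics = colMeans(fm), split = "test"),
            class = "eval_report")
}

#' Export a result matrix (datasets x configurations)
#'
#' One row per dataset, one column per configuration in grid order; the
#' CSV mirrors the heatmaps used to compare configurations. Missing cells
#' are left empty with a warning; duplicated cells are an error.
#'
#' @param reports List of `eval_report`s sharing a split.
#' @param metric One of `accuracy`, `f1`, `sensitivity`, `specificity`.
#' @param path Output CSV path.
#' @return The matrix, invisibly.
#' @export
export_result_matrix <- function(reports, metric = "f1", path) {
  stopifnot(length(reports) > 0L)
  if (length(unique(vapply(reports, `[[`, character(1L), "split"))) > 1L) {
    stop("reports must share a split")
  }
  ds <- vapply(reports, `[[`, character(1L), "dataset_name")
  cfg <- vapply(reports, function(r)
    paste(r$method, param_string(r$params), sep = "|"), character(1L))
  val <- vapply(reports, function(r) r$mean_metrics[[metric]], numeric(1L))
  rows <- unique(ds); cols <- unique(cfg)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_along(reports)) {
    if (!is.na(m[ds[i], cfg[i]])) {
      stop("duplicate (dataset, configuration): ", ds[i], " / ", cfg[i])
    }
    m[ds[i], cfg[i]] <- val[i]
  }
  if (anyNA(m)) warning("result matrix has empty cells")
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, na = "")
  invisible(m)
}

#' Read back a result matrix written by [export_result_matrix()]
#' @param path CSV path.
#' @return Numeric matrix with dataset row names.
#' @export
read_result_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}
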