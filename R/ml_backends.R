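# Classifier backends behind a uniform fit/predict contract.
#
# k-NN delegates to FNN; random forest, RBF-SVM and the single-hidden-
# layer neural network are implemented here (no dedicated ML package is
# assumed at run time). All fits are deterministic given `seed`.

#' Fit a binary classifier
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Label vector with exactly two classes.
#' @param method One of `"knn"`, `"rf"`, `"svm"`, `"ann"`.
#' @param params Named list of hyperparameters: knn `k`; rf `n_trees`,
#'   `leaf_size`; svm `penalty`, `kernel_width`; ann `n_neurons`,
#'   `epochs`, `momentum`, `learning_rate`.
#' @param seed Integer seed for any stochastic component (rf bootstrap,
#'   ann initialisation and shuffling).
#' @return A `phagehost_model` object usable with [predict_classifier()].
#' @export
fit_classifier <- function(x, y, method = c("knn", "rf", "svm", "ann"),
                           params = list(), seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.character(y)
  levels <- sort(unique(y))
  if (length(levels) != 2L) stop("binary classification requires 2 classes")
  yb <- ifelse(y == levels[2L], 1, -1)          # second (sorted) level = +1
  fit <- switch(method,
    knn = list(x = x, y = y, k = params$k %||% 3L),
    rf  = fit_rf(x, yb, n_trees = params$n_trees %||% 100L,
                 leaf_size = params$leaf_size %||% 2L, seed = seed),
    svm = fit_svm_rbf(x, yb, C = params$penalty %||% 1,
                      gamma = params$kernel_width %||% 1 / ncol(x)),
    ann = fit_mlp(x, (yb + 1) / 2, n_neurons = params$n_neurons %||% 5L,
                  epochs = params$epochs %||% 50L,
                  momentum = params$momentum %||% 0.1,
                  learning_rate = params$learning_rate %||% 1e-4,
                  seed = seed))
  structure(list(method = method, fit = fit, levels = levels),
            class = "phagehost_model")
}

#' Predict class labels
#'
#' @param model A `phagehost_model`.
#' @param x Feature matrix on the same scale as the training matrix.
#' @return Character vector of predicted labels.
#' @export
predict_classifier <- function(model, x) {
  x <- as.matrix(x)
  pred <- switch(model$method,
    knn = {
      cl <- factor(model$fit$y, levels = model$levels)
      as.character(FNN::knn(model$fit$x, x, cl,
                            k = min(model$fit$k, nrow(model$fit$x))))
    },
    rf  = ifelse(predict_rf(model$fit, x) > 0,
                 model$levels[2L], model$levels[1L]),
    svm = ifelse(predict_svm_rbf(model$fit, x) > 0,
                 model$levels[2L], model$levels[1L]),
    ann = ifelse(predict_mlp(model$fit, x) > 0.5,
                 model$levels[2L], model$levels[1L]))
  unname(pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- random forest (bagged CART, gini, random feature subsets) ----

fit_rf <- function(x, yb, n_trees, leaf_size, seed) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(x[idx, , drop = FALSE], yb[idx],
                            mtry = mtry, leaf_size = leaf_size)
  }
  list(trees = trees)
}

# a tree is a data.frame of nodes: feature, threshold, left, right, value
grow_tree <- function(x, yb, mtry, leaf_size, max_depth = 25L) {
  nodes <- list()
  build <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         value = mean(yb[rows]))
    n <- length(rows)
    if (depth >= max_depth || n < 2L * leaf_size ||
        all(yb[rows] == yb[rows][1L])) {
      return(id)
    }
    sp <- best_split(x[rows, , drop = FALSE], yb[rows], mtry, leaf_size)
    if (is.null(sp)) return(id)
    go_left <- x[rows, sp$feature] <= sp$threshold
    nodes[[id]]$feature <<- sp$feature
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$left <<- build(rows[go_left], depth + 1L)
    nodes[[id]]$right <<- build(rows[!go_left], depth + 1L)
    id
  }
  build(seq_along(yb), 0L)
  nodes
}

best_split <- function(x, yb, mtry, leaf_size) {
  n <- length(yb)
  pos <- yb > 0
  feats <- sample.int(ncol(x), min(mtry, ncol(x)))
  best <- NULL; best_imp <- Inf
  for (f in feats) {
    v <- x[, f]
    o <- order(v)
    vs <- v[o]; ps <- pos[o]
    cum_pos <- cumsum(ps)
    k <- seq_len(n - 1L)
    valid <- vs[k] < vs[k + 1L] & k >= leaf_size & (n - k) >= leaf_size
    if (!any(valid)) next
    kl <- k[valid]
    pl <- cum_pos[kl] / kl
    pr <- (cum_pos[n] - cum_pos[kl]) / (n - kl)
    imp <- kl * pl * (1 - pl) + (n - kl) * pr * (1 - pr)   # weighted gini/2
    j <- which.min(imp)
    if (imp[j] < best_imp) {
      best_imp <- imp[j]
      kk <- kl[j]
      best <- list(feature = f, threshold = (vs[kk] + vs[kk + 1L]) / 2)
    }
  }
  best
}

predict_tree <- function(nodes, x) {
  apply(x, 1L, function(row) {
    id <- 1L
    repeat {
      nd <- nodes[[id]]
      if (is.na(nd$feature)) return(nd$value)
      id <- if (row[nd$feature] <= nd$threshold) nd$left else nd$right
    }
  })
}

predict_rf <- function(fit, x) {
  votes <- rowMeans(vapply(fit$trees, predict_tree, numeric(nrow(x)), x = x))
  votes
}

## ---- RBF-kernel SVM (soft-margin dual via quadprog) ----

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

fit_svm_rbf <- function(x, yb, C, gamma) {
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  D <- (yb %o% yb) * K
  diag(D) <- diag(D) + 1e-8                     # numerical PD
  A <- cbind(yb, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n),
                            Amat = A, bvec = bvec, meq = 1L)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6
  # bias from margin vectors (0 < alpha < C), else all support vectors
  margin <- alpha > 1e-6 & alpha < C - 1e-6
  ref <- if (any(margin)) margin else sv
  f_no_b <- as.numeric(K %*% (alpha * yb))
  b <- mean(yb[ref] - f_no_b[ref])
  list(x = x[sv, , drop = FALSE], coef = (alpha * yb)[sv],
       b = b, gamma = gamma)
}

predict_svm_rbf <- function(fit, x) {
  K <- rbf_kernel(x, fit$x, fit$gamma)
  as.numeric(K %*% fit$coef) + fit$b
}

## ---- single-hidden-layer MLP, sigmoid units, SGD with momentum ----

sigmoid <- function(z) 1 / (1 + exp(-z))

fit_mlp <- function(x, y01, n_neurons, epochs, momentum, learning_rate,
                    seed, batch_size = 32L) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  w1 <- matrix(stats::rnorm(p * n_neurons, sd = 1 / sqrt(p)), p, n_neurons)
  b1 <- numeric(n_neurons)
  w2 <- matrix(stats::rnorm(n_neurons, sd = 1 / sqrt(n_neurons)), n_neurons, 1)
  b2 <- 0
  v_w1 <- w1 * 0; v_b1 <- b1 * 0; v_w2 <- w2 * 0; v_b2 <- 0
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[rows, , drop = FALSE]; yb <- y01[rows]
      h <- sigmoid(sweep(xb %*% w1, 2L, b1, "+"))
      out <- as.numeric(sigmoid(h %*% w2 + b2))
      # cross-entropy with sigmoid output: delta = out - y
      d_out <- (out - yb) / length(rows)
      g_w2 <- crossprod(h, d_out)
      g_b2 <- sum(d_out)
      d_h <- (d_out %o% as.numeric(w2)) * h * (1 - h)
      g_w1 <- crossprod(xb, d_h)
      g_b1 <- colSums(d_h)
      v_w1 <- momentum * v_w1 - learning_rate * g_w1
      v_b1 <- momentum * v_b1 - learning_rate * g_b1
      v_w2 <- momentum * v_w2 - learning_rate * g_w2
      v_b2 <- momentum * v_b2 - learning_rate * g_b2
      w1 <- w1 + v_w1; b1 <- b1 + v_b1; w2 <- w2 + v_w2; b2 <- b2 + v_b2
    }
  }
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

predict_mlp <- function(fit, x) {
  h <- sigmoid(sweep(x %*% fit$w1, 2L, fit$b1, "+"))
  as.numeric(sigmoid(h %*% fit$w2 + fit$b2))
}
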