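# RBF-kernel SVM training with (C, gamma) grid search, stratified k-fold
# cross-validation and sensitivity/specificity/accuracy reporting. The SVM
# itself is libsvm via e1071; scaling, fold construction, the grid protocol
# and the pooled-confusion metrics are defined here.

.as_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  y <- as.integer(y)
  stopifnot(is.matrix(x), nrow(x) == length(y), !anyNA(y))
  list(x = x, y = y)
}

#' Fit per-feature scaling to [-1, 1]
#'
#' Learns the per-feature affine map sending the training minimum to -1 and
#' maximum to +1 (libsvm practice). Constant features map to 0. The fitted
#' parameters are applied unchanged to test data, which may therefore fall
#' outside [-1, 1].
#'
#' @param x Numeric training matrix (or `feature_matrix`).
#' @return A `scaling_params` object.
#' @export
fit_scaling <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$x
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  structure(list(lo = lo, hi = hi, features = colnames(x)),
            class = "scaling_params")
}

#' Apply fitted scaling
#'
#' @param x Matrix with the same columns the scaling was fitted on.
#' @param sp A `scaling_params` object from [fit_scaling()].
#' @return The scaled matrix.
#' @export
apply_scaling <- function(x, sp) {
  stopifnot(inherits(sp, "scaling_params"))
  if (inherits(x, "feature_matrix")) x <- x$x
  if (!is.null(sp$features) && !is.null(colnames(x))) {
    if (!identical(colnames(x), sp$features)) {
      stop("feature schema mismatch between scaling and data")
    }
  }
  span <- sp$hi - sp$lo
  out <- x
  nc <- span > 0
  out[, nc] <- sweep(sweep(x[, nc, drop = FALSE], 2, sp$lo[nc]), 2,
                     span[nc] / 2, "/") - 1
  out[, !nc] <- 0
  out
}

# Stratified fold assignment: within each class, instances are shuffled
# under the seed and dealt round-robin into k folds.
.stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  if (min(table(y)) < k) {
    stop("k = ", k, " exceeds the minority-class size; reduce k")
  }
  folds <- integer(length(y))
  rng <- .seeded_rng(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[rng$sample_perm(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Local RNG helper: isolates package randomness from the global stream.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  env$sample_perm <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- sample.int(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  env
}

#' Compute sensitivity, specificity and accuracy from confusion counts
#'
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `ACC = (TP+TN)/(TP+FN+TN+FP)`. A metric whose denominator is zero (no
#' instance of that class evaluated) is returned as `NA` with a warning.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts (positives =
#'   thermophilic class).
#' @return List with `se`, `sp`, `acc` fractions in [0, 1] (or `NA`).
#' @export
evaluate_confusion <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  se <- if (tp + fn == 0) {
    warning("no positive instances: SE undefined"); NA_real_
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("no negative instances: SP undefined"); NA_real_
  } else tn / (tn + fp)
  list(se = se, sp = sp, acc = (tp + tn) / (tp + fn + tn + fp))
}

#' Train an RBF-kernel SVM
#'
#' Fits libsvm (C-classification, RBF kernel) on the full matrix after
#' fitting and applying [-1, 1] scaling. The returned model carries the
#' feature schema and scaling, so prediction takes raw (unscaled) feature
#' matrices with matching column names.
#'
#' @param x Feature matrix or labeled `feature_matrix`.
#' @param y Binary 0/1 labels (positive = 1).
#' @param cost Soft-margin cost C (> 0).
#' @param gamma RBF kernel width; default 1/ncol(x).
#' @param scale Fit min-max scaling to [-1, 1] (default); `FALSE` trains on
#'   raw features.
#' @return A `thermo_svm` model object.
#' @export
svm_train <- function(x, y = NULL, cost = 1, gamma = NULL, scale = TRUE) {
  d <- .as_xy(x, y)
  stopifnot(cost > 0)
  if (is.null(gamma)) gamma <- 1 / ncol(d$x)
  stopifnot(gamma > 0)
  sp <- if (scale) fit_scaling(d$x) else NULL
  xs <- if (scale) apply_scaling(d$x, sp) else d$x
  fit <- e1071::svm(xs, factor(d$y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, scaling = sp, features = colnames(d$x),
                 cost = cost, gamma = gamma),
            class = "thermo_svm")
}

#' Predict with a trained model
#'
#' @param object A `thermo_svm` model.
#' @param newdata Raw feature matrix (or `feature_matrix`) with exactly the
#'   training columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions, named by row.
#' @export
predict.thermo_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$features)) {
    stop("feature schema mismatch: model expects ",
         length(object$features), " named features in training order")
  }
  xs <- if (is.null(object$scaling)) newdata else
    apply_scaling(newdata, object$scaling)
  pred <- stats::predict(object$fit, xs)
  stats::setNames(as.integer(as.character(pred)), rownames(newdata))
}

#' Save / load a trained model
#'
#' The model is stored as a self-describing JSON-free R archive via
#' [saveRDS()]: schema, scaling parameters and the underlying SVM.
#'
#' @param model A `thermo_svm`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "thermo_svm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "thermo_svm"))
  m
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k stratified folds under the seed; for each fold,
#' scaling is fitted on the training partition only, an SVM is trained and
#' the held-out fold predicted. Every instance is predicted exactly once;
#' confusion counts are pooled over folds and summarized as SE/SP/ACC.
#'
#' @param x Feature matrix or labeled `feature_matrix`.
#' @param y Binary labels.
#' @param cost,gamma SVM parameters (gamma defaults to 1/ncol).
#' @param k Number of folds (>= 2, at most the minority-class size).
#' @param seed Integer seed for fold assignment.
#' @param scale Per-fold [-1, 1] scaling (default `TRUE`).
#' @return An `eval_report`: list with `confusion` (tp, fn, tn, fp), `se`,
#'   `sp`, `acc`, `folds` (per-fold accuracy), `params`, `seed`.
#' @export
cross_validate <- function(x, y = NULL, cost = 1, gamma = NULL, k = 10,
                           seed = 1L, scale = TRUE) {
  d <- .as_xy(x, y)
  if (is.null(gamma)) gamma <- 1 / ncol(d$x)
  folds <- .stratified_folds(d$y, k, seed)
  pred <- integer(length(d$y))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    if (length(unique(d$y[tr])) < 2) {
      stop("a class is absent from a training partition; ",
           "use fewer folds or another seed")
    }
    sp <- if (scale) fit_scaling(d$x[tr, , drop = FALSE]) else NULL
    xtr <- if (scale) apply_scaling(d$x[tr, , drop = FALSE], sp) else
      d$x[tr, , drop = FALSE]
    xte <- if (scale) apply_scaling(d$x[te, , drop = FALSE], sp) else
      d$x[te, , drop = FALSE]
    fit <- e1071::svm(xtr, factor(d$y[tr], levels = c(0, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    ph <- as.integer(as.character(stats::predict(fit, xte)))
    pred[te] <- ph
    fold_acc[f] <- mean(ph == d$y[te])
  }
  tp <- sum(pred == 1L & d$y == 1L)
  fn <- sum(pred == 0L & d$y == 1L)
  tn <- sum(pred == 0L & d$y == 0L)
  fp <- sum(pred == 1L & d$y == 0L)
  m <- evaluate_confusion(tp, fn, tn, fp)
  structure(list(confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 se = m$se, sp = m$sp, acc = m$acc,
                 folds = fold_acc,
                 params = list(cost = cost, gamma = gamma, k = k),
                 seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV (C=%g, gamma=%g)\n",
              x$params$k, x$params$cost, x$params$gamma))
  cat(sprintf("  SE = %.2f%%  SP = %.2f%%  ACC = %.2f%%\n",
              100 * x$se, 100 * x$sp, 100 * x$acc))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              x$confusion["tp"], x$confusion["fn"],
              x$confusion["tn"], x$confusion["fp"]))
  invisible(x)
}

#' Default (C, gamma) grid
#'
#' The libsvm grid-tool convention: C over 2^-5..2^15 and gamma over
#' 2^-15..2^3, both in steps of 2^2.
#'
#' @return List with numeric vectors `cost` and `gamma`.
#' @export
default_grid <- function() {
  list(cost = 2 ^ seq(-5, 15, by = 2), gamma = 2 ^ seq(-15, 3, by = 2))
}

#' Grid search for SVM parameters
#'
#' Evaluates stratified k-fold CV accuracy at every (C, gamma) grid point
#' and returns the maximizer; ties are broken toward smaller C, then
#' smaller gamma. The full grid table is returned for audit.
#'
#' @param x Feature matrix or labeled `feature_matrix`.
#' @param y Binary labels.
#' @param cost_grid,gamma_grid Candidate values (default [default_grid()]).
#' @param k Folds for the inner CV.
#' @param seed Fold seed (shared across grid points).
#' @param scale Per-fold scaling.
#' @return List with `cost`, `gamma`, `accuracy` (best point) and `table`
#'   (data frame of all points).
#' @export
grid_search <- function(x, y = NULL, cost_grid = default_grid()$cost,
                        gamma_grid = default_grid()$gamma, k = 5,
                        seed = 1L, scale = TRUE) {
  d <- .as_xy(x, y)
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cross_validate(d$x, d$y, cost = grid$cost[i], gamma = grid$gamma[i],
                   k = k, seed = seed, scale = scale)$acc
  }, numeric(1))
  # ties toward smaller C then smaller gamma
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1], ]
  list(cost = best$cost, gamma = best$gamma, accuracy = best$accuracy,
       table = grid)
}

#' Write an evaluation report as JSON
#'
#' Percentages are carried at 2-decimal precision alongside the raw
#' fractions, confusion counts, per-fold accuracies, parameters and seed.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  obj <- list(
    confusion = as.list(report$confusion),
    se = report$se, sp = report$sp, acc = report$acc,
    se_pct = round(100 * report$se, 2),
    sp_pct = round(100 * report$sp, 2),
    acc_pct = round(100 * report$acc, 2),
    fold_accuracy = report$folds,
    params = report$params,
    seed = report$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
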