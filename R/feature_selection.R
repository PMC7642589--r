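# Ensemble feature ranking fused by a PageRank-style graph walk, followed by
# forward-adding search for the accuracy-optimal prefix size.

.ranking_methods <- c("anova", "mi", "mrmr", "lasso", "pearson", "chisq",
                      "relief")

#' Available feature-ranking methods
#'
#' Seven per-feature relevance rankers fused by [fuse_pagerank()]:
#' `anova` (one-way F statistic), `mi` (mutual information with equal-width
#' binning), `mrmr` (greedy minimal-redundancy maximal-relevance), `lasso`
#' (L1-regularized logistic coefficient magnitude at a fixed path point),
#' `pearson` (point-biserial correlation magnitude), `chisq` (chi-squared on
#' quartile-binned features) and `relief` (deterministic ReliefF, k = 5).
#'
#' @return Character vector of method names.
#' @export
ranking_methods <- function() .ranking_methods

.new_ranking <- function(feature, score, method, canonical) {
  structure(data.frame(feature = feature, score = score,
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"),
            method = method, canonical = canonical)
}

# Order scores descending with stable canonical-order tie-break; constant
# columns carry score 0 and are forced to the tail in canonical order.
.order_ranking <- function(features, score, method, constant) {
  score[constant] <- 0
  key <- ifelse(constant, -Inf, score)
  ord <- order(-key, seq_along(features))
  .new_ranking(features[ord], score[ord], method, features)
}

# Vectorized two-class one-way ANOVA F per column; ties at zero within-class
# variance are capped to keep scores finite.
.anova_f <- function(x, y) {
  i1 <- y == 1L
  n0 <- sum(!i1); n1 <- sum(i1); n <- n0 + n1
  m0 <- colMeans(x[!i1, , drop = FALSE])
  m1 <- colMeans(x[i1, , drop = FALSE])
  gm <- colMeans(x)
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  v0 <- apply(x[!i1, , drop = FALSE], 2, stats::var)
  v1 <- apply(x[i1, , drop = FALSE], 2, stats::var)
  ssw <- (n0 - 1) * v0 + (n1 - 1) * v1
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssb == 0] <- 0
  f[!is.finite(f)] <- 1e300
  f
}

.binned_mi <- function(x, y, nbins = 10) {
  apply(x, 2, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(0)
    b <- findInterval(v, seq(rng[1], rng[2], length.out = nbins + 1),
                      rightmost.closed = TRUE, all.inside = TRUE)
    tab <- table(b, y)
    p <- tab / sum(tab)
    pr <- rowSums(p); pc <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(pr, pc)[nz]))
  })
}

# Greedy mRMR: relevance = ANOVA F (rescaled to [0,1]), redundancy = mean
# absolute Pearson correlation with the already-selected set. The ranking is
# the greedy selection order; the stored score is relevance - redundancy at
# selection time.
.mrmr_rank <- function(x, y) {
  p <- ncol(x)
  rel <- .anova_f(x, y)
  if (max(rel) > 0) rel <- rel / max(rel)
  sds <- apply(x, 2, stats::sd)
  selected <- integer(0)
  scores <- numeric(p)
  red_sum <- numeric(p)
  remaining <- seq_len(p)
  for (step in seq_len(p)) {
    red <- if (length(selected) == 0) 0 else red_sum[remaining] / length(selected)
    obj <- rel[remaining] - red
    pick <- remaining[which.max(obj)]
    scores[pick] <- max(obj)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0 && sds[pick] > 0) {
      r <- abs(suppressWarnings(
        stats::cor(x[, remaining, drop = FALSE], x[, pick])))
      r[is.na(r)] <- 0
      red_sum[remaining] <- red_sum[remaining] + as.vector(r)
    }
  }
  list(order = selected, score = scores)
}

.lasso_score <- function(x, y) {
  if (ncol(x) < 2) {
    r <- abs(suppressWarnings(stats::cor(x[, 1], y)))
    return(ifelse(is.na(r), 0, r))
  }
  fit <- glmnet::glmnet(x, factor(y), family = "binomial",
                        standardize = TRUE, nlambda = 100)
  # fixed path point: the smallest lambda glmnet computed (densest model)
  beta <- fit$beta[, ncol(fit$beta)]
  abs(as.vector(beta))
}

.pearson_score <- function(x, y) {
  r <- abs(suppressWarnings(stats::cor(x, y)))
  r[is.na(r)] <- 0
  as.vector(r)
}

.chisq_score <- function(x, y) {
  apply(x, 2, function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, 0.25)))
    if (length(br) < 2) return(0)
    b <- cut(v, breaks = br, include.lowest = TRUE)
    suppressWarnings(stats::chisq.test(table(b, y))$statistic)
  })
}

# Deterministic ReliefF: every instance is a probe; features are min-max
# normalized; k nearest hits and misses by Manhattan distance.
.relief_score <- function(x, y, k = 5) {
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  keep <- span > 0
  if (!any(keep)) return(numeric(p))
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, rng[1, keep]), 2,
             span[keep], "/")
  d <- as.matrix(stats::dist(z, method = "manhattan"))
  w <- numeric(sum(keep))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    kh <- same[order(d[i, same], same)][seq_len(min(k, length(same)))]
    km <- diff[order(d[i, diff], diff)][seq_len(min(k, length(diff)))]
    di <- abs(sweep(z[c(kh, km), , drop = FALSE], 2, z[i, ]))
    nh <- length(kh)
    hit <- if (nh > 0) colMeans(di[seq_len(nh), , drop = FALSE]) else 0
    miss <- colMeans(di[nh + seq_len(length(km)), , drop = FALSE])
    w <- w + (miss - hit)
  }
  out <- numeric(p)
  out[keep] <- w / n
  out
}

#' Rank features by a single relevance method
#'
#' Produces a deterministic full ordering of the feature columns, best
#' first. Ties are broken by the canonical column order; constant columns
#' score 0 and sink to the tail.
#'
#' @param x Numeric feature matrix (columns named) or a `feature_matrix`.
#' @param y Binary 0/1 label vector (ignored with a labeled
#'   `feature_matrix`).
#' @param method One of [ranking_methods()].
#' @return A `feature_ranking`: data frame with columns `feature`, `score`,
#'   ordered best first.
#' @export
rank_features <- function(x, y = NULL, method = "anova") {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  y <- as.integer(y)
  if (length(unique(y)) != 2) stop("both classes must be present")
  if (!(method %in% .ranking_methods)) {
    stop("unknown ranking method '", method, "'; valid: ",
         paste(.ranking_methods, collapse = ", "))
  }
  feats <- colnames(x)
  constant <- apply(x, 2, function(v) max(v) == min(v))
  if (method == "mrmr") {
    res <- .mrmr_rank(x, y)
    ord <- res$order
    # move constant columns to the tail, preserving canonical order there
    ord <- c(ord[!constant[ord]], which(constant))
    sc <- res$score; sc[constant] <- 0
    return(.new_ranking(feats[ord], sc[ord], method, feats))
  }
  score <- switch(method,
    anova   = .anova_f(x, y),
    mi      = .binned_mi(x, y),
    lasso   = .lasso_score(x, y),
    pearson = .pearson_score(x, y),
    chisq   = .chisq_score(x, y),
    relief  = .relief_score(x, y))
  score <- as.numeric(score)
  score[!is.finite(score)] <- 0
  .order_ranking(feats, score, method, constant)
}

#' Fuse rankings with a PageRank graph walk
#'
#' Builds an endorsement graph over the common feature set: within each
#' ranking, every feature casts a unit-weight directed edge to each feature
#' ranked above it (lower endorses higher, transitively). The stationary
#' PageRank distribution of that graph — damping `d`, dangling mass spread
#' uniformly — orders the fused ranking; weights sum to 1. For a single
#' ranking the fused order reproduces the input order, and a feature placed
#' first by every ranker collects endorsements from all other features and
#' dominates the stationary distribution.
#'
#' @param rankings A list of `feature_ranking` objects over the same
#'   feature set.
#' @param damping Damping factor in (0, 1).
#' @param tol Convergence tolerance on the L1 change per iteration.
#' @param max_iter Maximum power iterations.
#' @return A `feature_ranking` with PageRank weights as scores.
#' @export
fuse_pagerank <- function(rankings, damping = 0.85, tol = 1e-10,
                          max_iter = 10000) {
  if (inherits(rankings, "feature_ranking")) rankings <- list(rankings)
  stopifnot(length(rankings) >= 1)
  canonical <- attr(rankings[[1]], "canonical")
  feats <- sort(canonical)
  for (r in rankings) {
    if (!identical(sort(r$feature), feats)) {
      stop("rankings cover different feature sets")
    }
  }
  n <- length(canonical)
  idx <- stats::setNames(seq_len(n), canonical)
  w <- matrix(0, n, n)  # w[i, j]: edge weight i -> j
  for (r in rankings) {
    ord <- idx[r$feature]
    for (j in seq_len(n)[-1]) {
      above <- ord[seq_len(j - 1)]
      w[ord[j], above] <- w[ord[j], above] + 1
    }
  }
  out_w <- rowSums(w)
  pr <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    dangling <- sum(pr[out_w == 0])
    flow <- as.vector(crossprod(w, ifelse(out_w > 0, pr / out_w, 0)))
    new <- (1 - damping) / n + damping * (flow + dangling / n)
    if (sum(abs(new - pr)) < tol) {
      pr <- new
      break
    }
    pr <- new
  }
  pr <- pr / sum(pr)
  ord <- order(-pr, seq_len(n))
  .new_ranking(canonical[ord], pr[ord], "pagerank_fusion", canonical)
}

#' Forward-adding search for the accuracy-optimal prefix
#'
#' Walks the fused ranking from the top, evaluating the cross-validated
#' accuracy of each feature-count prefix, and returns the smallest prefix
#' attaining the maximum accuracy. Prefix sizes advance by `step` up to
#' `dense_limit` features and by `sparse_step` beyond (the full set is
#' always evaluated).
#'
#' @param x Numeric feature matrix or `feature_matrix`.
#' @param y Binary labels (ignored with a labeled `feature_matrix`).
#' @param ranking A `feature_ranking` over the columns of `x`.
#' @param evaluator Function `(x_subset, y) -> accuracy fraction`; defaults
#'   to stratified 5-fold SVM cross-validation with default parameters and
#'   a fixed internal seed.
#' @param step Prefix-size increment in the dense region.
#' @param dense_limit Size up to which `step` applies.
#' @param sparse_step Increment beyond `dense_limit`.
#' @return A `selection_result`: list with `fused` ranking, `sizes`,
#'   `accuracy_curve`, `best_size`, `best_accuracy`, `selected_features`.
#' @export
forward_select <- function(x, y = NULL, ranking, evaluator = NULL, step = 1,
                           dense_limit = 200, sparse_step = 5) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  stopifnot(is.matrix(x), ncol(x) > 0, nrow(x) > 0)
  y <- as.integer(y)
  if (is.null(evaluator)) {
    evaluator <- function(xs, ys) {
      cross_validate(xs, ys, k = 5, seed = 20201022L)$acc
    }
  }
  p <- ncol(x)
  sizes <- seq(1, min(p, dense_limit), by = step)
  if (p > dense_limit) {
    sizes <- c(sizes, seq(dense_limit + sparse_step, p, by = sparse_step))
  }
  sizes <- sort(unique(c(sizes, p)))
  acc <- vapply(sizes, function(s) {
    sub <- x[, ranking$feature[seq_len(s)], drop = FALSE]
    evaluator(sub, y)
  }, numeric(1))
  best_i <- which.max(acc)          # which.max takes the first (smallest) max
  best_size <- sizes[best_i]
  structure(list(fused = ranking, sizes = sizes, accuracy_curve = acc,
                 best_size = best_size, best_accuracy = acc[best_i],
                 selected_features = ranking$feature[seq_len(best_size)]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> best %d/%d features, CV accuracy %.4f\n",
              x$best_size, length(x$fused$feature), x$best_accuracy))
  cat("  top features:",
      paste(utils::head(x$fused$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Rank, fuse and forward-select in one step
#'
#' The full selection pipeline: rank the features with each requested
#' method, fuse the rankings with [fuse_pagerank()], then locate the
#' accuracy-optimal prefix with [forward_select()].
#'
#' @param fm A labeled `feature_matrix` (or a matrix plus `y`).
#' @param y Binary labels when `fm` is a bare matrix.
#' @param methods Ranking methods to ensemble (default: all seven).
#' @param damping PageRank damping factor.
#' @param evaluator Optional accuracy callback passed to [forward_select()].
#' @param step Dense-region prefix increment.
#' @return A `selection_result` (with the per-method rankings attached as
#'   attribute `rankings`).
#' @export
select_features <- function(fm, y = NULL, methods = ranking_methods(),
                            damping = 0.85, evaluator = NULL, step = 1) {
  if (inherits(fm, "feature_matrix")) {
    if (is.null(y)) y <- fm$y
    x <- fm$x
  } else {
    x <- fm
  }
  rankings <- lapply(methods, function(m) rank_features(x, y, m))
  fused <- fuse_pagerank(rankings, damping = damping)
  res <- forward_select(x, y, fused, evaluator = evaluator, step = step)
  attr(res, "rankings") <- rankings
  res
}

#' Serialize a selection result to JSON
#'
#' Writes the fused ranking with weights, the accuracy curve and the
#' selected feature names.
#'
#' @param res A `selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(res, path) {
  obj <- list(
    fused_ranking = data.frame(feature = res$fused$feature,
                               weight = res$fused$score),
    accuracy_curve = data.frame(size = res$sizes,
                                accuracy = res$accuracy_curve),
    best_size = res$best_size,
    best_accuracy = res$best_accuracy,
    selected_features = res$selected_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a feature-importance ranking as TSV
#'
#' Two columns: 1-based rank and feature name.
#'
#' @param ranking A `feature_ranking`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(data.frame(rank = seq_along(ranking$feature),
                                feature = ranking$feature),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
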