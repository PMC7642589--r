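# A tiny labeled matrix with one perfectly separating feature, one noise
# feature and one constant feature.
toy_matrix <- function(n = 30, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(sep = y + stats::rnorm(n, sd = 0.05),
             noise = stats::rnorm(n),
             const = rep(1, n))
  list(x = x, y = y)
}

test_that("every method ranks a separating feature above noise and constants", {
  d <- toy_matrix()
  for (m in ranking_methods()) {
    r <- rank_features(d$x, d$y, m)
    expect_equal(r$feature[1], "sep", info = m)
    expect_equal(r$feature[3], "const", info = m)  # constants sink to tail
    expect_equal(r$score[r$feature == "const"], 0, info = m)
    expect_true(all(is.finite(r$score)), info = m)
    expect_setequal(r$feature, colnames(d$x))
  }
  expect_error(rank_features(d$x, d$y, "nope"), "unknown ranking method")
  expect_error(rank_features(d$x, rep(1L, nrow(d$x)), "anova"),
               "both classes")
})

test_that("ANOVA F statistic matches the hand-computed one-way oracle", {
  x <- cbind(toy = c(1, 2, 3, 7, 8, 9), pad = c(0, 1, 0, 1, 0, 1))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  r <- rank_features(x, y, "anova")
  expect_equal(r$score[r$feature == "toy"], 54)
  # cross-check against the stats machinery on the same column
  fit <- stats::anova(stats::lm(x[, "toy"] ~ factor(y)))
  expect_equal(r$score[r$feature == "toy"], fit$`F value`[1])
})

test_that("identical class distributions give near-zero ANOVA score", {
  set.seed(21)
  x <- cbind(null = rnorm(200), strong = rep(c(0, 3), each = 100))
  y <- rep(c(0L, 1L), each = 100)
  r <- rank_features(x, y, "anova")
  expect_equal(r$feature[1], "strong")
  expect_lt(r$score[r$feature == "null"] / r$score[r$feature == "strong"],
            0.05)
})

test_that("PageRank fusion: consensus identity and probability weights", {
  d <- toy_matrix()
  r1 <- rank_features(d$x, d$y, "anova")
  # single ranking -> same order
  f1 <- fuse_pagerank(r1)
  expect_equal(f1$feature, r1$feature)
  # identical rankings -> same order, weights sum to 1
  f2 <- fuse_pagerank(list(r1, r1, r1))
  expect_equal(f2$feature, r1$feature)
  expect_equal(sum(f2$score), 1)
  # mismatched feature sets rejected
  r_other <- rank_features(d$x[, 1:2], d$y, "anova")
  expect_error(fuse_pagerank(list(r1, r_other)), "different feature sets")
})

test_that("fusion weights match a dense power-iteration oracle", {
  mk <- function(f) structure(data.frame(feature = f,
                                         score = rev(seq_along(f))),
                              class = c("feature_ranking", "data.frame"),
                              method = "toy", canonical = c("A", "B", "C"))
  fused <- fuse_pagerank(list(mk(c("A", "B", "C")), mk(c("A", "C", "B"))))
  # oracle graph: each feature endorses everything ranked above it
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["B", "A"] <- w["B", "A"] + 1; w["C", "A"] <- w["C", "A"] + 1
  w["C", "B"] <- w["C", "B"] + 1                      # ranking ABC
  w["C", "A"] <- w["C", "A"] + 1; w["B", "A"] <- w["B", "A"] + 1
  w["B", "C"] <- w["B", "C"] + 1                      # ranking ACB
  pr <- oracle_pagerank(w)
  expect_equal(fused$score[match(c("A", "B", "C"), fused$feature)],
               pr, tolerance = 1e-8)
  expect_equal(fused$feature[1], "A")
})

test_that("fusion is equivariant under feature relabeling", {
  d <- toy_matrix(seed = 6)
  rks <- lapply(c("anova", "pearson", "mi"),
                function(m) rank_features(d$x, d$y, m))
  f <- fuse_pagerank(rks)
  # relabel columns and refuse
  x2 <- d$x
  colnames(x2) <- c("zz_sep", "aa_noise", "mm_const")
  rks2 <- lapply(c("anova", "pearson", "mi"),
                 function(m) rank_features(x2, d$y, m))
  f2 <- fuse_pagerank(rks2)
  relabel <- c(sep = "zz_sep", noise = "aa_noise", const = "mm_const")
  expect_equal(unname(relabel[f$feature]), f2$feature)
  expect_equal(f$score, f2$score, tolerance = 1e-12)
})

test_that("forward adding finds the smallest prefix at maximum accuracy", {
  d <- toy_matrix(n = 40, seed = 12)
  # put 9 extra noise columns behind the separator
  set.seed(13)
  x <- cbind(d$x[, "sep", drop = FALSE],
             matrix(rnorm(40 * 9), 40, dimnames = list(NULL, paste0("n", 1:9))))
  r <- rank_features(x, d$y, "anova")
  expect_equal(r$feature[1], "sep")
  res <- forward_select(x, d$y, r)
  expect_equal(res$best_size, 1)
  expect_equal(res$best_accuracy, 1)
  expect_equal(res$selected_features, "sep")
  # contract: curve covers the sizes, best is its max, prefix consistency
  expect_equal(length(res$accuracy_curve), length(res$sizes))
  expect_equal(res$best_accuracy, max(res$accuracy_curve))
  expect_equal(res$best_size,
               res$sizes[which.max(res$accuracy_curve)])
  expect_equal(res$selected_features,
               res$fused$feature[seq_len(res$best_size)])
})

test_that("forward adding honors a custom evaluator and tie-breaks small", {
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0L, 1L), 10)
  r <- rank_features(x, y, "pearson")
  # evaluator with a plateau: sizes 2 and 3 tie at the maximum
  ev <- function(xs, ys) c(0.5, 0.9, 0.9)[ncol(xs)]
  res <- forward_select(x, y, r, evaluator = ev)
  expect_equal(res$best_size, 2)
  expect_equal(res$best_accuracy, 0.9)
})

test_that("planted informative features are recovered by selection", {
  hits <- 0
  reps <- 20
  for (s in 1:reps) {
    set.seed(100 + s)
    n <- 160
    y <- rep(c(0L, 1L), each = n / 2)
    x <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
    informative <- c("f03", "f11", "f17")
    for (f in informative) x[, f] <- x[, f] + 2 * y   # 2 SD shift
    res <- select_features(x, y, methods = c("anova", "pearson", "mi"),
                           step = 1)
    if (all(informative %in% res$selected_features)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("selection pipeline runs with a single ranking method", {
  d <- toy_matrix(n = 20, seed = 30)
  res <- select_features(d$x, d$y, methods = "anova")
  expect_s3_class(res, "selection_result")
  expect_equal(res$fused$feature[1], "sep")
})

test_that("selection result serializes to JSON and TSV", {
  d <- toy_matrix(n = 20, seed = 31)
  res <- select_features(d$x, d$y, methods = "anova")
  f <- withr::local_tempfile(fileext = ".json")
  write_selection_json(res, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_named(obj, c("fused_ranking", "accuracy_curve", "best_size",
                      "best_accuracy", "selected_features"),
               ignore.order = TRUE)
  expect_equal(obj$best_size, res$best_size)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_tsv(res$fused, f2)
  tab <- read.table(f2, sep = "\t")
  expect_equal(tab$V2, res$fused$feature)
})

test_that("ranking is deterministic for fixed input", {
  d <- toy_matrix(n = 40, seed = 44)
  for (m in ranking_methods()) {
    expect_identical(rank_features(d$x, d$y, m),
                     rank_features(d$x, d$y, m), info = m)
  }
})
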