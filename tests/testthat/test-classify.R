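test_that("SE/SP/accuracy follow their formulas including 0/0 conventions", {
  expect_warning(m <- compute_metrics(c(TP = 50, TN = 0, FP = 0, FN = 50)), "SP")
  expect_equal(m[["SE"]], 0.5)
  m2 <- compute_metrics(c(TP = 90, TN = 94, FP = 25, FN = 19))
  expect_equal(m2[["accuracy"]], 184 / 228)
  expect_warning(m3 <- compute_metrics(c(TP = 0, TN = 10, FP = 0, FN = 0)), "SE")
  expect_equal(m3[["SE"]], 0)
  expect_equal(m3[["SP"]], 1)
  expect_error(compute_metrics(c(TP = -1, TN = 1, FP = 0, FN = 0)), "non-negative")
})

test_that("accuracy decomposes as the prevalence-weighted mean of SE and SP", {
  withr::local_seed(91)
  for (i in 1:25) {
    cnt <- c(TP = sample(0:40, 1), TN = sample(1:40, 1),
             FP = sample(0:40, 1), FN = sample(1:40, 1))
    m <- suppressWarnings(compute_metrics(cnt))
    P <- cnt[["TP"]] + cnt[["FN"]]
    N <- cnt[["TN"]] + cnt[["FP"]]
    expect_equal(m[["accuracy"]], (m[["SE"]] * P + m[["SP"]] * N) / (P + N))
  }
})

test_that("a threshold-separable 1D problem yields a depth-1 perfect tree", {
  x <- cbind(f = c(1, 3, 5, 8, 10, 12, 15, 20))
  y <- as.integer(x[, 1] >= 10)
  fm <- make_fm(x, y)
  tree <- train_tree(fm, min_leaf = 1)
  expect_equal(tree$root$type, "split")
  expect_equal(tree$root$left$type, "leaf")
  expect_equal(tree$root$right$type, "leaf")
  pred <- predict(tree, fm)
  expect_equal(as.integer(pred == "positive"), y)
})

test_that("single-class data yields a single-leaf tree predicting that class", {
  fm <- make_fm(cbind(f = rnorm(6)), rep(1, 6))
  tree <- train_tree(fm)
  expect_equal(tree$root$type, "leaf")
  expect_true(all(predict(tree, fm) == "positive"))
})

test_that("XOR needs depth 2 and the tree attains it with min_leaf 1", {
  pts <- cbind(a = c(0, 0, 0, 1, 1, 1),
               b = c(0, 1, 1, 0, 1, 1))
  y <- as.integer(xor(pts[, 1], pts[, 2] > 0))
  fm <- make_fm(pts, y)
  # brute force: no single axis-aligned split separates XOR
  best1 <- oracle_root_split(fm$values, y, min_leaf = 1)
  one_split_acc <- 0
  for (f in 1:2) for (thr in unique(fm$values[, f])) {
    for (hi in c(0, 1)) {
      pred <- ifelse(fm$values[, f] <= thr, hi, 1 - hi)
      one_split_acc <- max(one_split_acc, mean(pred == y))
    }
  }
  expect_lt(one_split_acc, 1)
  tree <- train_tree(fm, min_leaf = 1)
  expect_gte(tree_depth_for_test(tree), 2L)
  expect_true(all(as.integer(predict(tree, fm) == "positive") == y))
})

test_that("the root split equals exhaustive gain-ratio search on random data", {
  withr::local_seed(101)
  for (i in 1:120) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    v <- matrix(sample(0:5, n * p, replace = TRUE) + rnorm(n * p, sd = 1e-3),
                n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    fm <- make_fm(v, y)
    tree <- train_tree(fm, min_leaf = 2, max_depth = 1)
    oracle <- oracle_root_split(v, y, min_leaf = 2)
    if (is.null(oracle)) {
      expect_equal(tree$root$type, "leaf")
    } else {
      expect_equal(tree$root$feature_index, oracle$feature)
      expect_equal(tree$root$threshold, oracle$threshold, tolerance = 1e-12)
      expect_equal(tree$root$gain_ratio, oracle$gain_ratio, tolerance = 1e-10)
    }
  }
})

test_that("forest reduces to a single tree and is seed-deterministic", {
  withr::local_seed(111)
  v <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(v[, 1] + 0.3 * rnorm(40) > 0)
  fm <- make_fm(v, y)
  single <- train_forest(fm, n_trees = 1, mtry = 3, min_leaf = 2,
                         bootstrap = FALSE, seed = 5)
  tree <- train_tree(fm, min_leaf = 2)
  newv <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_equal(predict(single, newv), predict(tree, newv))
  f1 <- train_forest(fm, n_trees = 25, seed = 9)
  f2 <- train_forest(fm, n_trees = 25, seed = 9)
  expect_equal(predict(f1, newv), predict(f2, newv))
})

test_that("a separable problem gives perfect out-of-bag accuracy", {
  x <- cbind(f = c(seq(0, 1, length.out = 12), seq(10, 11, length.out = 12)))
  y <- rep(c(0, 1), each = 12)
  fm <- make_fm(x, y)
  fst <- train_forest(fm, n_trees = 25, seed = 3)
  expect_equal(fst$oob_accuracy, 1)
})

test_that("cross-validation partitions samples and is exact on separable data", {
  withr::local_seed(121)
  x <- cbind(f = c(rnorm(30, 0), rnorm(30, 20)))
  y <- rep(c(0, 1), each = 30)
  fm <- make_fm(x, y)
  rep10 <- cross_validate(fm, k = 10, seed = 4)
  expect_equal(sum(rep10$pooled), 60)
  expect_equal(colSums(as.matrix(rep10$folds[, c("TP", "TN", "FP", "FN")])),
               rep10$pooled)
  expect_equal(unname(rep10$metrics["accuracy"]), 1)
  expect_error(cross_validate(make_fm(x[1:12, , drop = FALSE], y[c(1:6, 31:36)]),
                              k = 10),
               "smaller k")
})

test_that("fold assignment is a stratified partition for every seed tried", {
  y <- c(rep(0, 23), rep(1, 17))
  fm <- make_fm(cbind(f = seq_along(y)), y)
  for (seed in 1:5) {
    rep5 <- cross_validate(fm, k = 5, seed = seed)
    expect_equal(sum(rep5$pooled), 40)  # each sample tested exactly once
  }
})
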