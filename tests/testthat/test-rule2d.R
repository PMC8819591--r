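test_that("scatter counts match the features module on every record", {
  recs <- data.frame(
    id = c("a", "b", "c"),
    seq = c("ISNVTREDAGTYTC", strrep("GAC", 10), strrep("W", 5)),
    label = c("positive", "negative", "negative"),
    stringsAsFactors = FALSE)
  tab <- scatter_table(recs, feat_x = "F*C", feat_y = "G*C")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$x[1], 1L)  # reduced motif VGGVGGGGGGGFGC has one F*C
  expect_equal(tab$y[1], 0L)
  # cross-module consistency against gapped_dipeptide_counts
  for (i in seq_len(nrow(recs))) {
    cnt <- gapped_dipeptide_counts(reduce_sequence(recs$seq[i]), 1)
    expect_equal(tab$x[i], cnt[["F*C"]])
    expect_equal(tab$y[i], cnt[["G*C"]])
  }
  expect_true(all(tab$x >= 0) && all(tab$x == round(tab$x)))
  # feature letters absent from the sequence give zero counts
  expect_equal(unlist(tab[tab$id == "c", c("x", "y")], use.names = FALSE), c(0L, 0L))
  expect_error(scatter_table(recs, feat_x = "Z*Q"), "scheme alphabet|cannot parse")
})

test_that("alias names select the same scatter features", {
  recs <- data.frame(id = "a", seq = "ISNVTREDAGTYTC", label = "positive",
                     stringsAsFactors = FALSE)
  t1 <- scatter_table(recs, feat_x = "F*C", feat_y = "G*C")
  t2 <- scatter_table(recs, feat_x = "FC*", feat_y = "GC*")
  expect_equal(t1[, c("x", "y")], t2[, c("x", "y")])
})

test_that("a separable construction is fit with training accuracy 1", {
  tab <- data.frame(
    id = paste0("s", 1:10),
    x = c(1, 2, 3, 1, 2, 0, 0, 0, 0, 0),
    y = c(0, 1, 2, 2, 1, 5, 6, 7, 8, 9),
    label = rep(c("positive", "negative"), each = 5),
    stringsAsFactors = FALSE)
  rule <- fit_rule(tab)
  expect_equal(rule$accuracy, 1)
  expect_equal(sum(rule$counts), 10)
  expect_equal(rule$counts[["TP"]] + rule$counts[["TN"]], 10)
})

test_that("fitted rule equals an independent exhaustive enumeration", {
  withr::local_seed(161)
  best_by_enumeration <- function(tab) {
    y01 <- as.integer(tab$label == "positive")
    best <- -1
    for (tx in sort(unique(tab$x))) for (ty in sort(unique(tab$y))) {
      for (inv in c(FALSE, TRUE)) for (xh in c(TRUE, FALSE)) for (yh in c(TRUE, FALSE)) {
        inside <- (if (xh) tab$x > tx else tab$x <= tx) &
                  (if (yh) tab$y > ty else tab$y <= ty)
        pred <- as.integer(if (inv) !inside else inside)
        best <- max(best, mean(pred == y01))
      }
    }
    best
  }
  for (i in 1:15) {
    tab <- data.frame(id = paste0("s", 1:20),
                      x = sample(0:6, 20, replace = TRUE),
                      y = sample(0:12, 20, replace = TRUE),
                      label = sample(c("positive", "negative"), 20,
                                     replace = TRUE),
                      stringsAsFactors = FALSE)
    if (length(unique(tab$label)) < 2) next
    rule <- fit_rule(tab)
    expect_equal(rule$accuracy, best_by_enumeration(tab))
    # rule never does worse than the best single-threshold rule alone
    single_best <- 0
    y01 <- as.integer(tab$label == "positive")
    for (feat in c("x", "y")) for (thr in unique(tab[[feat]])) {
      for (hi in c(TRUE, FALSE)) {
        pred <- if (hi) tab[[feat]] > thr else tab[[feat]] <= thr
        single_best <- max(single_best, mean(as.integer(pred) == y01))
      }
    }
    expect_gte(rule$accuracy + 1e-12, single_best)
  }
})

test_that("swapping class labels inverts the rule at the same thresholds", {
  withr::local_seed(171)
  tab <- data.frame(id = paste0("s", 1:24),
                    x = sample(0:5, 24, replace = TRUE),
                    y = sample(0:9, 24, replace = TRUE),
                    label = rep(c("positive", "negative"), 12),
                    stringsAsFactors = FALSE)
  swapped <- tab
  swapped$label <- ifelse(tab$label == "positive", "negative", "positive")
  r1 <- fit_rule(tab)
  r2 <- fit_rule(swapped)
  expect_equal(r2$x_threshold, r1$x_threshold)
  expect_equal(r2$y_threshold, r1$y_threshold)
  expect_equal(r2$x_high, r1$x_high)
  expect_equal(r2$y_high, r1$y_high)
  expect_equal(r2$invert, !r1$invert)
  expect_equal(r2$accuracy, r1$accuracy)
})

test_that("class summaries report exact order statistics and zero counts", {
  tab <- data.frame(id = paste0("s", 1:6),
                    x = c(0, 0, 3, 1, 2, 5), y = c(1, 1, 1, 0, 0, 4),
                    label = c("negative", "negative", "negative",
                              "positive", "positive", "positive"),
                    stringsAsFactors = FALSE)
  sm <- class_summaries(tab)
  neg_x <- sm[sm$label == "negative" & sm$feature == "x", ]
  expect_equal(neg_x$n_zero, 2L)
  expect_equal(neg_x$max, 3)
  expect_equal(neg_x$min, 0)
  # empty table gives an empty summary, not an error
  expect_equal(nrow(class_summaries(tab[0, ])), 0L)
})

test_that("single-class or unlabeled tables are rejected", {
  tab <- data.frame(id = c("a", "b"), x = c(1, 2), y = c(3, 4),
                    label = c("positive", "positive"), stringsAsFactors = FALSE)
  expect_error(fit_rule(tab), "both classes")
  tab$label <- NA_character_
  expect_error(fit_rule(tab), "label")
})
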