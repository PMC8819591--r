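#' Confusion counts from truth and prediction
#'
#' @param truth,predicted Class vectors (factor negative/positive, logical,
#'   or 0/1), positive class = immunoglobulin = 1.
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  yt <- labels01(truth)
  yp <- labels01(predicted)
  stopifnot(length(yt) == length(yp))
  c(TP = sum(yt == 1L & yp == 1L), TN = sum(yt == 0L & yp == 0L),
    FP = sum(yt == 0L & yp == 1L), FN = sum(yt == 1L & yp == 0L))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' SE = TP/(TP+FN), SP = TN/(TN+FP), Accuracy = (TP+TN)/(TP+FN+TN+FP).
#' A 0/0 ratio is defined as 0, with a warning.
#'
#' @param counts Named vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `SE`, `SP`, `accuracy`.
#' @export
#' @examples
#' compute_metrics(c(TP = 50, TN = 40, FP = 5, FN = 5))
compute_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts)) stop("counts must provide TP, TN, FP, FN")
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (0/0); returning 0", what))
      return(0)
    }
    num / den
  }
  se <- safe_ratio(counts[["TP"]], counts[["TP"]] + counts[["FN"]], "SE")
  sp <- safe_ratio(counts[["TN"]], counts[["TN"]] + counts[["FP"]], "SP")
  acc <- safe_ratio(counts[["TP"]] + counts[["TN"]], sum(counts), "accuracy")
  c(SE = se, SP = sp, accuracy = acc)
}

# Binary entropy (bits) of a node with `pos` positives out of `n`.
# Vectorized; 0 log 0 = 0.
binary_entropy <- function(pos, n) {
  p <- pos / n
  q <- 1 - p
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + q[ok] * log2(q[ok]))
  h
}

# Best gain-ratio split over the given feature columns. Candidate thresholds
# are midpoints between adjacent distinct sorted values; candidates must
# leave at least min_leaf samples on each side and have positive information
# gain. Ties break toward the lower feature index, then the lower threshold.
find_best_split <- function(values, y, feat_idx, min_leaf) {
  n <- length(y)
  P <- sum(y)
  h_parent <- binary_entropy(P, n)
  best <- NULL
  for (f in sort(feat_idx)) {
    v <- values[, f]
    o <- order(v, method = "radix")
    vs <- v[o]
    ys <- y[o]
    cum_pos <- cumsum(ys)
    i <- seq_len(n - 1L)
    ok <- vs[i] < vs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(ok)) next
    i <- i[ok]
    nl <- i
    nr <- n - i
    pl <- cum_pos[i]
    pr <- P - pl
    gain <- h_parent - (nl * binary_entropy(pl, nl) + nr * binary_entropy(pr, nr)) / n
    split_info <- binary_entropy(nl, n)  # two-way split entropy of sizes
    gr <- gain / split_info
    keep <- gain > 1e-12
    if (!any(keep)) next
    grk <- gr
    grk[!keep] <- -Inf
    # sub-tolerance gain-ratio differences are ties: keep the lowest threshold
    j <- which(grk >= max(grk) - 1e-12)[1L]
    cand <- list(feature = f,
                 threshold = unname(vs[i[j]] + vs[i[j] + 1L]) / 2,
                 gain_ratio = unname(gr[j]), gain = unname(gain[j]))
    if (is.null(best) || cand$gain_ratio > best$gain_ratio + 1e-12) best <- cand
  }
  best
}

grow_tree <- function(values, y, min_leaf, max_depth, mtry, depth = 0L) {
  n <- length(y)
  pos <- sum(y)
  make_leaf <- function() {
    list(type = "leaf",
         prediction = if (pos > n - pos) 1L else 0L,  # tie -> negative
         n_pos = pos, n_neg = n - pos)
  }
  if (pos == 0L || pos == n || depth >= max_depth || n < 2L * min_leaf) {
    return(make_leaf())
  }
  p <- ncol(values)
  feat_idx <- seq_len(p)
  if (!is.null(mtry) && mtry < p) {
    feat_idx <- sample.int(p, mtry)
  }
  split <- find_best_split(values, y, feat_idx, min_leaf)
  if (is.null(split)) return(make_leaf())
  left <- values[, split$feature] <= split$threshold
  list(type = "split",
       feature = colnames(values)[split$feature],
       feature_index = split$feature,
       threshold = split$threshold,
       gain_ratio = split$gain_ratio,
       left = grow_tree(values[left, , drop = FALSE], y[left],
                        min_leaf, max_depth, mtry, depth + 1L),
       right = grow_tree(values[!left, , drop = FALSE], y[!left],
                         min_leaf, max_depth, mtry, depth + 1L))
}

#' Train a gain-ratio decision tree
#'
#' A C4.5-family tree: univariate binary splits on numeric features, chosen
#' to maximize the gain ratio over midpoint thresholds of sorted feature
#' values; growth stops on node purity, `min_leaf`, or `max_depth`. Leaves
#' predict the majority class, ties going to the negative class. No pruning
#' is applied.
#'
#' @param fm A labeled `feature_matrix` with at least 2 samples (a
#'   single-class matrix yields a single-leaf tree).
#' @param min_leaf Minimum samples on each side of a split (default 2).
#' @param max_depth Optional depth limit (default unlimited).
#' @return A `gr_tree` model.
#' @export
train_tree <- function(fm, min_leaf = 2L, max_depth = Inf) {
  stopifnot(nrow(fm$values) >= 1L, min_leaf >= 1L)
  if (is.null(fm$labels)) stop("feature matrix must be labeled")
  y <- labels01(fm$labels)
  root <- grow_tree(fm$values, y, as.integer(min_leaf), max_depth, mtry = NULL)
  structure(list(root = root, features = colnames(fm$values),
                 min_leaf = min_leaf, max_depth = max_depth),
            class = "gr_tree")
}

route_tree <- function(node, values) {
  n <- nrow(values)
  out <- integer(n)
  if (n == 0L) return(out)
  if (node$type == "leaf") {
    out[] <- node$prediction
    return(out)
  }
  left <- values[, node$feature] <= node$threshold
  out[left] <- route_tree(node$left, values[left, , drop = FALSE])
  out[!left] <- route_tree(node$right, values[!left, , drop = FALSE])
  out
}

#' @export
predict.gr_tree <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  missing <- setdiff(object$features, colnames(values))
  if (length(missing)) stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  pred <- route_tree(object$root, values[, object$features, drop = FALSE])
  factor(c("negative", "positive")[pred + 1L], levels = c("negative", "positive"))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.gr_tree <- function(x, ...) {
  cat(sprintf("gain-ratio tree: %d feature(s), depth %d\n",
              length(x$features), tree_depth(x$root)))
  invisible(x)
}

#' Train a random-forest analogue of gain-ratio trees
#'
#' Grows `n_trees` unpruned gain-ratio trees on bootstrap resamples, each
#' split restricted to `mtry` features drawn at random per node; prediction
#' is the majority vote, ties going to the negative class. Fully determined
#' by `seed`.
#'
#' @param fm A labeled `feature_matrix`.
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split; default `round(sqrt(p))`.
#' @param min_leaf Minimum leaf size per tree (default 1, fully grown).
#' @param seed Integer seed governing bootstraps and feature draws.
#' @param bootstrap Set `FALSE` to train every tree on the full sample
#'   (with `n_trees = 1, mtry = p` this reduces to [train_tree()]).
#' @return A `gr_forest` with elements `trees`, `oob_accuracy` (NA without
#'   bootstrap), `seed`.
#' @export
train_forest <- function(fm, n_trees = 100L, mtry = NULL, min_leaf = 1L,
                         seed = 1L, bootstrap = TRUE) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled")
  values <- fm$values
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(mtry)) mtry <- max(1L, as.integer(round(sqrt(p))))
  y <- labels01(fm$labels)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  trees <- vector("list", n_trees)
  oob_votes <- matrix(0L, n, 2L)  # columns: negative, positive
  for (t in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    root <- grow_tree(values[idx, , drop = FALSE], y[idx],
                      as.integer(min_leaf), Inf,
                      mtry = if (mtry < p) mtry else NULL)
    trees[[t]] <- root
    if (bootstrap) {
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob)) {
        pred <- route_tree(root, values[oob, , drop = FALSE])
        for (cls in 0:1) {
          hit <- oob[pred == cls]
          oob_votes[hit, cls + 1L] <- oob_votes[hit, cls + 1L] + 1L
        }
      }
    }
  }
  oob_acc <- NA_real_
  if (bootstrap) {
    voted <- rowSums(oob_votes) > 0L
    if (any(voted)) {
      oob_pred <- as.integer(oob_votes[voted, 2L] > oob_votes[voted, 1L])  # tie -> negative
      oob_acc <- mean(oob_pred == y[voted])
    }
  }
  structure(list(trees = trees, features = colnames(values), n_trees = n_trees,
                 mtry = mtry, seed = seed, bootstrap = bootstrap,
                 oob_accuracy = oob_acc),
            class = "gr_forest")
}

#' @export
predict.gr_forest <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "feature_matrix")) newdata$values else newdata
  values <- values[, object$features, drop = FALSE]
  votes <- matrix(0L, nrow(values), 2L)
  for (root in object$trees) {
    pred <- route_tree(root, values)
    votes[, 1L] <- votes[, 1L] + (pred == 0L)
    votes[, 2L] <- votes[, 2L] + (pred == 1L)
  }
  pred <- as.integer(votes[, 2L] > votes[, 1L])  # tie -> negative
  factor(c("negative", "positive")[pred + 1L], levels = c("negative", "positive"))
}

#' @export
print.gr_forest <- function(x, ...) {
  cat(sprintf("gain-ratio forest: %d trees, mtry %d, OOB accuracy %s\n",
              x$n_trees, x$mtry,
              if (is.na(x$oob_accuracy)) "NA" else sprintf("%.3f", x$oob_accuracy)))
  invisible(x)
}

# Stratified fold assignment: seeded shuffle within each class, folds dealt
# round-robin. Returns an integer vector of fold ids per sample.
stratified_folds <- function(labels, k, seed) {
  y <- labels01(labels)
  fold <- integer(length(y))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (cls in 0:1) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop(sprintf("class %d has %d samples, fewer than k = %d folds; use a smaller k",
                   cls, length(idx), k))
    }
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

fit_model <- function(fm, model, fold_seed) {
  type <- model$type %||% "tree"
  if (type == "tree") {
    train_tree(fm, min_leaf = model$min_leaf %||% 2L,
               max_depth = model$max_depth %||% Inf)
  } else if (type == "forest") {
    train_forest(fm, n_trees = model$n_trees %||% 100L,
                 mtry = model$mtry, min_leaf = model$min_leaf %||% 1L,
                 seed = fold_seed)
  } else {
    stop("unknown model type: ", type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validation
#'
#' Folds are assigned by a seeded shuffle within each class; every sample is
#' predicted exactly once. Per-fold and pooled confusion counts are reported
#' with SE/SP/accuracy computed from the pooled counts.
#'
#' @param fm A labeled `feature_matrix`; each class needs at least `k`
#'   members.
#' @param model List describing the classifier: `type` `"tree"` or
#'   `"forest"` plus its parameters (`min_leaf`, `max_depth`, `n_trees`,
#'   `mtry`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold shuffling (and, derived, forest
#'   training per fold).
#' @return A `cv_report`: list with `folds` (data frame of per-fold counts),
#'   `pooled` counts, `metrics` (SE, SP, accuracy), `k`, `seed`.
#' @export
cross_validate <- function(fm, model = list(type = "tree"), k = 10L, seed = 1L) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled")
  stopifnot(k >= 2L)
  fold <- stratified_folds(fm$labels, k, seed)
  per_fold <- matrix(0L, k, 4L, dimnames = list(NULL, c("TP", "TN", "FP", "FN")))
  for (f in seq_len(k)) {
    test <- fold == f
    train_fm <- feature_matrix(fm$values[!test, , drop = FALSE], fm$labels[!test])
    fit <- fit_model(train_fm, model, fold_seed = seed * 1000L + f)
    pred <- predict(fit, fm$values[test, , drop = FALSE])
    per_fold[f, ] <- confusion_counts(fm$labels[test], pred)
  }
  pooled <- colSums(per_fold)
  structure(list(folds = cbind(data.frame(fold = seq_len(k)), as.data.frame(per_fold)),
                 pooled = pooled, metrics = compute_metrics(pooled),
                 k = k, seed = seed, model = model),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s, seed %d): SE %.3f, SP %.3f, accuracy %.3f\n",
              x$k, x$model$type %||% "tree", x$seed,
              x$metrics[["SE"]], x$metrics[["SP"]], x$metrics[["accuracy"]]))
  cat(sprintf("pooled counts: TP %d, TN %d, FP %d, FN %d\n",
              x$pooled[["TP"]], x$pooled[["TN"]], x$pooled[["FP"]], x$pooled[["FN"]]))
  invisible(x)
}

#' Cross-validated accuracy callback
#'
#' Convenience factory used by [select_subset()] and [backward_eliminate()]:
#' returns a function mapping a `feature_matrix` to its k-fold CV accuracy
#' under a fixed model and seed.
#'
#' @inheritParams cross_validate
#' @return Function `feature_matrix -> accuracy`.
#' @export
cv_evaluator <- function(model = list(type = "tree"), k = 10L, seed = 1L) {
  force(model); force(k); force(seed)
  function(fm) unname(cross_validate(fm, model, k, seed)$metrics["accuracy"])
}

#' Write a CV report as TSV
#'
#' Per-fold counts plus a pooled row and the three metrics as comment
#' header lines.
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d-fold CV, model=%s, seed=%d", report$k,
                     report$model$type %||% "tree", report$seed), con)
  writeLines(sprintf("# SE=%.6f SP=%.6f accuracy=%.6f",
                     report$metrics[["SE"]], report$metrics[["SP"]],
                     report$metrics[["accuracy"]]), con)
  df <- rbind(report$folds,
              data.frame(fold = NA, t(as.matrix(report$pooled))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
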