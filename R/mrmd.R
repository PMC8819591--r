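# Standardize columns to mean 0, unit variance; zero-variance columns become
# all-zero so they contribute neither relevance nor similarity.
standardize_columns <- function(values) {
  mu <- colMeans(values)
  s <- apply(values, 2L, stats::sd)
  s[s == 0] <- Inf
  sweep(sweep(values, 2L, mu), 2L, s, "/")
}

labels01 <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels == "positive"))
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  if (is.character(labels)) return(as.integer(labels == "positive"))
  stop("cannot interpret labels")
}

#' MRMD relevance of one feature column
#'
#' Absolute Pearson correlation between the column and the class labels
#' encoded 0/1; a zero-variance column has relevance 0 by convention.
#'
#' @param column Numeric vector.
#' @param labels Class labels (factor negative/positive, logical, or 0/1).
#' @return Value in \[0, 1\].
#' @export
mrmd_relevance <- function(column, labels) {
  y <- labels01(labels)
  if (length(column) != length(y)) stop("column and labels differ in length")
  if (length(y) < 2L) stop("need at least 2 samples")
  if (stats::sd(column) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(column, y))
}

tanimoto_coefficient <- function(x, y) {
  denom <- sum(x^2) + sum(y^2) - sum(x * y)
  if (denom == 0) return(1)  # both zero vectors: identical
  sum(x * y) / denom
}

# Pairwise distance matrix between standardized columns under one metric.
column_distances <- function(Z, metric = c("cosine", "euclidean", "tanimoto")) {
  metric <- match.arg(metric)
  p <- ncol(Z)
  if (metric == "euclidean") return(as.matrix(stats::dist(t(Z))))
  G <- crossprod(Z)
  nrm2 <- diag(G)
  if (metric == "cosine") {
    denom <- sqrt(outer(nrm2, nrm2))
    S <- ifelse(denom == 0, 0, G / ifelse(denom == 0, 1, denom))
    diag(S) <- 1
    return(1 - S)
  }
  denom <- outer(nrm2, nrm2, "+") - G
  S <- ifelse(denom == 0, 1, G / ifelse(denom == 0, 1, denom))
  1 - S
}

#' MRMD distance term of one feature
#'
#' Mean distance from the (standardized) feature column to every other
#' column under the chosen metric; 0 for a single-feature matrix.
#'
#' @param index Feature column index.
#' @param fm A `feature_matrix`.
#' @param metric One of `"euclidean"`, `"cosine"`, `"tanimoto"` (cosine and
#'   tanimoto are 1 minus the respective similarity).
#' @return Non-negative value.
#' @export
mrmd_distance <- function(index, fm, metric = c("cosine", "euclidean", "tanimoto")) {
  metric <- match.arg(metric)
  values <- fm$values
  p <- ncol(values)
  if (p < 2L) return(0)
  D <- column_distances(standardize_columns(values), metric)
  sum(D[index, -index]) / (p - 1L)
}

#' Max-relevance-max-distance (MRMD) feature ranking
#'
#' Scores every feature as `w_r * relevance + w_d * distance`, where
#' relevance is the absolute Pearson correlation with the class and distance
#' is the mean pairwise distance to all other standardized feature columns.
#' Features are ranked by descending score; ties break by original column
#' index.
#'
#' @param fm A labeled `feature_matrix`.
#' @param weights Numeric `(w_r, w_d)`, default `c(1, 1)`.
#' @param metric Distance metric, see [mrmd_distance()].
#' @return An `mrmd_ranking` data frame with columns `feature`, `relevance`,
#'   `distance`, `score`, `rank` (rows in original column order).
#' @export
mrmd_rank <- function(fm, weights = c(1, 1),
                      metric = c("cosine", "euclidean", "tanimoto")) {
  metric <- match.arg(metric)
  if (is.null(fm$labels)) stop("feature matrix must be labeled for MRMD ranking")
  stopifnot(length(weights) == 2L)
  values <- fm$values
  p <- ncol(values)
  y <- labels01(fm$labels)
  rel <- apply(values, 2L, function(col) {
    if (stats::sd(col) == 0) 0 else abs(stats::cor(col, y))
  })
  if (p >= 2L) {
    D <- column_distances(standardize_columns(values), metric)
    dst <- (rowSums(D) - diag(D)) / (p - 1L)
  } else {
    dst <- 0
  }
  score <- weights[1] * rel + weights[2] * dst
  ord <- order(-score, seq_len(p))
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  out <- data.frame(feature = colnames(values), relevance = unname(rel),
                    distance = unname(dst), score = unname(score),
                    rank = rank, stringsAsFactors = FALSE)
  structure(out, class = c("mrmd_ranking", "data.frame"),
            weights = weights, metric = metric)
}

#' Features of a ranking in rank order
#'
#' @param ranking An `mrmd_ranking`.
#' @return Character vector of feature names, best first.
#' @export
ranked_features <- function(ranking) {
  ranking$feature[order(ranking$rank)]
}

#' Incremental subset selection over an MRMD ranking
#'
#' Evaluates the nested prefixes top-1, top-2, ..., top-`k_max` of the
#' ranking with a cross-validated accuracy callback and returns the smallest
#' prefix whose accuracy is within `tolerance` of the best prefix accuracy.
#'
#' @param fm A labeled `feature_matrix`.
#' @param ranking An `mrmd_ranking` for `fm`.
#' @param evaluator Function taking a `feature_matrix` and returning an
#'   accuracy in \[0, 1\] (see [cv_evaluator()]).
#' @param k_max Largest prefix size to evaluate.
#' @param tolerance Accuracy slack below the best prefix (default 0.005).
#' @return List with `features` (selected subset, in rank order), `k`,
#'   `best_accuracy`, `accuracy`, and `trajectory` (data frame `k`,
#'   `feature_added`, `accuracy`).
#' @export
select_subset <- function(fm, ranking, evaluator,
                          k_max = min(30L, ncol(fm$values)),
                          tolerance = 0.005) {
  stopifnot(k_max >= 1L, k_max <= ncol(fm$values))
  feats <- ranked_features(ranking)
  acc <- numeric(k_max)
  for (k in seq_len(k_max)) {
    acc[k] <- evaluator(fm_subset(fm, feats[seq_len(k)]))
  }
  best <- max(acc)
  k_sel <- which(acc >= best - tolerance)[1]
  list(features = feats[seq_len(k_sel)], k = k_sel,
       best_accuracy = best, accuracy = acc[k_sel],
       trajectory = data.frame(k = seq_len(k_max),
                               feature_added = feats[seq_len(k_max)],
                               accuracy = acc, stringsAsFactors = FALSE))
}
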