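#' Greedy backward elimination to a minimal feature subset
#'
#' Starting from all features of `fm`, repeatedly removes the single feature
#' whose removal maximizes the evaluator accuracy. Ties break toward
#' removing the feature with the lower MRMD score when a `ranking` is
#' supplied, otherwise toward the later column. Elimination stops when the
#' best removal would drop accuracy by more than `tolerance` below the best
#' accuracy seen so far, or when `min_features` is reached. With
#' `tolerance = Inf` the elimination always runs down to exactly
#' `min_features` features, accepting any accuracy drop on the way — the
#' mode used to force a minimal interpretable model.
#'
#' @param fm A labeled `feature_matrix`.
#' @param evaluator Accuracy callback, see [cv_evaluator()].
#' @param min_features Smallest subset size to reach (default 2).
#' @param tolerance Largest tolerated drop below the best accuracy seen.
#' @param ranking Optional `mrmd_ranking` used for tie-breaking.
#' @return List with `features` (final subset), `accuracy` (final subset's
#'   evaluator accuracy), and `trajectory` (data frame `step`,
#'   `removed_feature`, `n_features`, `accuracy`; step 0 is the full set).
#' @export
backward_eliminate <- function(fm, evaluator, min_features = 2L,
                               tolerance = 0, ranking = NULL) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled")
  stopifnot(min_features >= 1L)
  current <- colnames(fm$values)
  scores <- NULL
  if (!is.null(ranking)) {
    scores <- stats::setNames(ranking$score, ranking$feature)
  }
  acc <- evaluator(fm)
  best_seen <- acc
  traj <- data.frame(step = 0L, removed_feature = NA_character_,
                     n_features = length(current), accuracy = acc,
                     stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > min_features) {
    cand_acc <- vapply(current, function(f) {
      evaluator(fm_subset(fm, setdiff(current, f)))
    }, numeric(1))
    m <- max(cand_acc)
    if (m < best_seen - tolerance) break
    tied <- names(cand_acc)[cand_acc >= m - 1e-12]
    remove <- if (!is.null(scores) && all(tied %in% names(scores))) {
      tied[which.min(scores[tied])]
    } else {
      tied[length(tied)]  # later column removed first
    }
    current <- setdiff(current, remove)
    best_seen <- max(best_seen, m)
    step <- step + 1L
    traj <- rbind(traj, data.frame(step = step, removed_feature = remove,
                                   n_features = length(current),
                                   accuracy = cand_acc[[remove]],
                                   stringsAsFactors = FALSE))
  }
  list(features = current, accuracy = traj$accuracy[nrow(traj)],
       trajectory = traj)
}

#' Greedy forward selection (alternative direction)
#'
#' Adds, at each step, the feature whose addition maximizes evaluator
#' accuracy, up to `max_features` features or until no addition improves
#' accuracy by more than `tolerance`.
#'
#' @inheritParams backward_eliminate
#' @param max_features Largest subset size to build.
#' @return List with `features`, `accuracy`, `trajectory` (data frame
#'   `step`, `added_feature`, `n_features`, `accuracy`).
#' @export
forward_select <- function(fm, evaluator, max_features = 2L,
                           tolerance = 0, ranking = NULL) {
  if (is.null(fm$labels)) stop("feature matrix must be labeled")
  all_feats <- colnames(fm$values)
  scores <- NULL
  if (!is.null(ranking)) scores <- stats::setNames(ranking$score, ranking$feature)
  current <- character(0)
  best_seen <- -Inf
  traj <- data.frame(step = integer(0), added_feature = character(0),
                     n_features = integer(0), accuracy = numeric(0),
                     stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) < max_features) {
    remaining <- setdiff(all_feats, current)
    cand_acc <- vapply(remaining, function(f) {
      evaluator(fm_subset(fm, c(current, f)))
    }, numeric(1))
    m <- max(cand_acc)
    if (length(current) > 0L && m < best_seen - tolerance) break
    tied <- names(cand_acc)[cand_acc >= m - 1e-12]
    add <- if (!is.null(scores) && all(tied %in% names(scores))) {
      tied[which.max(scores[tied])]
    } else {
      tied[1L]
    }
    current <- c(current, add)
    best_seen <- max(best_seen, m)
    step <- step + 1L
    traj <- rbind(traj, data.frame(step = step, added_feature = add,
                                   n_features = length(current),
                                   accuracy = cand_acc[[add]],
                                   stringsAsFactors = FALSE))
  }
  list(features = current, accuracy = traj$accuracy[nrow(traj)],
       trajectory = traj)
}
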