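#' Two-feature scatter table of raw dipeptide counts
#'
#' For every record, the raw integer counts of two gapped-dipeptide features
#' on the reduced sequence. Raw counts (not frequencies) are used because
#' integer thresholds on counts are directly interpretable.
#'
#' @param records Data frame with columns `id`, `seq` and optionally
#'   `label`.
#' @param scheme Reduction scheme.
#' @param feat_x,feat_y Gapped-dipeptide feature names (aliases like
#'   `"FC*"` accepted, see [parse_dipeptide()]).
#' @return Data frame `id`, `x`, `y`, `label` in record order.
#' @export
scatter_table <- function(records, scheme = default_scheme(),
                          feat_x = "F*C", feat_y = "G*C") {
  scheme <- as_scheme(scheme)
  alphabet <- scheme_alphabet(scheme)
  fx <- parse_dipeptide(feat_x)
  fy <- parse_dipeptide(feat_y)
  for (f in list(fx, fy)) {
    if (!f$first %in% alphabet || !f$second %in% alphabet) {
      stop("feature letters not in the scheme alphabet: ", f$canonical)
    }
  }
  reduced <- reduce_sequence(records$seq, scheme)
  count_one <- function(f) {
    vapply(reduced, function(rs) {
      gapped_dipeptide_counts(rs, f$gap, alphabet)[[f$canonical]]
    }, integer(1), USE.NAMES = FALSE)
  }
  data.frame(id = records$id, x = count_one(fx), y = count_one(fy),
             label = if ("label" %in% names(records)) records$label else NA_character_,
             stringsAsFactors = FALSE)
}

rule_predict <- function(x, y, rule) {
  px <- if (rule$x_high) x > rule$x_threshold else x <= rule$x_threshold
  py <- if (rule$y_high) y > rule$y_threshold else y <= rule$y_threshold
  inside <- px & py
  if (isTRUE(rule$invert)) inside <- !inside
  as.integer(inside)
}

#' Fit an axis-aligned two-threshold rule
#'
#' Exhaustively searches integer thresholds over the observed count ranges,
#' the four half-plane orientations, and both decision polarities for the
#' rule "positive iff inside (or outside) the quadrant (x above/below
#' x_threshold) and (y above/below y_threshold)" with maximal training
#' accuracy. Ties break toward smaller thresholds, then toward the
#' non-inverted orientation calling the positive class at high x. Because
#' the family is closed under complement, swapping the class labels returns
#' the same thresholds with inverted decision logic.
#'
#' @param table Labeled scatter table from [scatter_table()], both classes
#'   present.
#' @return A `threshold_rule`: list with `x_threshold`, `y_threshold`,
#'   `x_high`, `y_high` (logical: does the quadrant lie above the
#'   threshold?), `invert` (is the positive class outside the quadrant?),
#'   `counts` (training [confusion_counts()]) and `accuracy`.
#' @export
fit_rule <- function(table) {
  if (all(is.na(table$label))) stop("scatter table must be labeled")
  y01 <- labels01(table$label)
  if (length(unique(y01)) < 2L) stop("both classes must be present to fit a rule")
  xs <- sort(unique(table$x))
  ys <- sort(unique(table$y))
  best <- NULL
  # Iteration order encodes the tie-break: thresholds ascending, then the
  # non-inverted high-x orientation before the alternatives.
  for (tx in xs) for (ty in ys) {
    for (invert in c(FALSE, TRUE)) {
      for (x_high in c(TRUE, FALSE)) for (y_high in c(FALSE, TRUE)) {
        rule <- list(x_threshold = tx, y_threshold = ty,
                     x_high = x_high, y_high = y_high, invert = invert)
        acc <- mean(rule_predict(table$x, table$y, rule) == y01)
        if (is.null(best) || acc > best$accuracy + 1e-12) {
          rule$accuracy <- acc
          best <- rule
        }
      }
    }
  }
  pred <- rule_predict(table$x, table$y, best)
  best$counts <- confusion_counts(y01, pred)
  class(best) <- "threshold_rule"
  best
}

#' @export
print.threshold_rule <- function(x, ...) {
  side <- function(high) if (high) ">" else "<="
  cat(sprintf("threshold rule: positive iff %s(x %s %d and y %s %d) (training accuracy %.3f)\n",
              if (isTRUE(x$invert)) "not " else "",
              side(x$x_high), x$x_threshold, side(x$y_high), x$y_threshold,
              x$accuracy))
  invisible(x)
}

#' Per-class order statistics of the two scatter features
#'
#' @param table Labeled scatter table.
#' @return Data frame with one row per class and feature: `label`,
#'   `feature`, `n`, `n_zero`, `min`, `q25`, `median`, `q75`, `max`. Classes
#'   absent from the table simply contribute no rows.
#' @export
class_summaries <- function(table) {
  out <- NULL
  for (lab in unique(table$label[!is.na(table$label)])) {
    sub <- table[table$label == lab, , drop = FALSE]
    for (feat in c("x", "y")) {
      v <- sub[[feat]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
      out <- rbind(out, data.frame(
        label = lab, feature = feat, n = length(v), n_zero = sum(v == 0),
        min = min(v), q25 = q[1], median = q[2], q75 = q[3], max = max(v),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(label = character(0), feature = character(0),
                      n = integer(0), n_zero = integer(0), min = numeric(0),
                      q25 = numeric(0), median = numeric(0), q75 = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
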