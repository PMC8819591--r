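#' Hamming-tolerant motif scan
#'
#' Slides the motif along each sequence and counts windows whose Hamming
#' distance to the motif is at most `max_mismatches`; overlapping windows
#' all count. A motif longer than a sequence gives 0 occurrences.
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param motif Amino-acid string.
#' @param max_mismatches Allowed mismatches per window (default 0).
#' @return Data frame `id`, `occurrences`, `best_position` (1-based start of
#'   the first window with the fewest mismatches; NA when the motif does not
#'   fit), `min_mismatches`; attribute `n_hit` holds the number of records
#'   with at least one occurrence.
#' @export
#' @examples
#' recs <- data.frame(id = "a", seq = "ISNVTREDAGTYTC")
#' scan_motif(recs, "ISNVTREDAGTYTC")$occurrences  # 1
scan_motif <- function(records, motif, max_mismatches = 0L) {
  stopifnot(is.character(motif), nzchar(motif), max_mismatches >= 0L)
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  res <- lapply(records$seq, function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- length(ch)
    if (L < k) {
      return(list(occurrences = 0L, best_position = NA_integer_,
                  min_mismatches = NA_integer_))
    }
    n_win <- L - k + 1L
    mism <- integer(n_win)
    for (j in seq_len(k)) {
      mism <- mism + (ch[j:(j + n_win - 1L)] != m[j])
    }
    list(occurrences = sum(mism <= max_mismatches),
         best_position = which.min(mism),
         min_mismatches = min(mism))
  })
  out <- data.frame(id = records$id,
                    occurrences = vapply(res, `[[`, integer(1), "occurrences"),
                    best_position = vapply(res, `[[`, integer(1), "best_position"),
                    min_mismatches = vapply(res, `[[`, integer(1), "min_mismatches"),
                    stringsAsFactors = FALSE)
  attr(out, "n_hit") <- sum(out$occurrences > 0L)
  out
}

#' Gapped-dipeptide contribution of a motif
#'
#' How many occurrences of a gapped-dipeptide feature the motif itself
#' contributes once reduced: the feature's count within
#' `reduce_sequence(motif, scheme)`. This quantifies why a conserved motif
#' drives a reduced-alphabet feature — e.g. the ...Y-T-C tail of an
#' immunoglobulin-domain motif reduces to F-G-C and contributes one F*C
#' (lambda = 1) occurrence.
#'
#' @param motif Amino-acid string.
#' @param scheme Reduction scheme.
#' @param feature Gapped-dipeptide feature name (aliases accepted).
#' @return Integer count (0 when the motif is shorter than lambda + 2).
#' @export
#' @examples
#' motif_feature_contribution("ISNVTREDAGTYTC", default_scheme(), "F*C")  # 1
motif_feature_contribution <- function(motif, scheme = default_scheme(), feature) {
  scheme <- as_scheme(scheme)
  f <- parse_dipeptide(feature)
  reduced <- reduce_sequence(motif, scheme)
  counts <- gapped_dipeptide_counts(reduced, f$gap, scheme_alphabet(scheme))
  if (!f$canonical %in% names(counts)) {
    stop("feature letters not in the scheme alphabet: ", f$canonical)
  }
  counts[[f$canonical]]
}
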