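#' Canonical name of a lambda-gap dipeptide feature
#'
#' The canonical form writes the gap as asterisks between the two letters:
#' `"GC"` (lambda = 0), `"F*C"` (lambda = 1), `"G**C"` (lambda = 2).
#'
#' @param first,second Single representative letters.
#' @param gap Non-negative integer gap (lambda).
#' @return Feature name string.
#' @export
dipeptide_name <- function(first, second, gap = 0L) {
  stopifnot(gap >= 0L)
  paste0(first, strrep("*", gap), second)
}

#' Parse a gapped-dipeptide feature name
#'
#' Accepts the canonical infix form (`"F*C"`) and, for fidelity to common
#' shorthand, the trailing-asterisk alias (`"FC*"` is read as `"F*C"`,
#' `"FC**"` as `"F**C"`).
#'
#' @param name Feature name string.
#' @return List with elements `first`, `second`, `gap`, `canonical`.
#' @export
#' @examples
#' parse_dipeptide("FC*")$canonical  # "F*C"
parse_dipeptide <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  x <- gsub("\\s", "", name)
  if (grepl("^[A-Z]\\*+[A-Z]$", x)) {
    first <- substr(x, 1L, 1L)
    second <- substr(x, nchar(x), nchar(x))
    gap <- nchar(x) - 2L
  } else if (grepl("^[A-Z]{2}\\**$", x)) {
    first <- substr(x, 1L, 1L)
    second <- substr(x, 2L, 2L)
    gap <- nchar(x) - 2L
  } else {
    stop("cannot parse dipeptide feature name: ", name)
  }
  list(first = first, second = second, gap = gap,
       canonical = dipeptide_name(first, second, gap))
}

#' Count lambda-gap dipeptides in a reduced sequence
#'
#' A lambda-gap dipeptide of type (a, b) occurs at position i when
#' `seq[i] == a` and `seq[i + gap + 1] == b`. A sequence of length L has
#' `max(0, L - gap - 1)` such positions; sequences shorter than `gap + 2`
#' give all-zero counts.
#'
#' @param reduced_seq A single reduced sequence string.
#' @param gap Non-negative integer gap (lambda).
#' @param alphabet Ordered character vector of letters over which counts are
#'   reported (default: letters present in the default scheme).
#' @return Named integer vector over all ordered letter pairs, first letter
#'   major, named with [dipeptide_name()].
#' @export
#' @examples
#' gapped_dipeptide_counts("VGGVGGGGGGGFGC", gap = 1)[["F*C"]]  # 1
gapped_dipeptide_counts <- function(reduced_seq, gap = 0L,
                                    alphabet = scheme_alphabet(default_scheme())) {
  stopifnot(length(reduced_seq) == 1L, gap >= 0L)
  gap <- as.integer(gap)
  nm <- as.vector(t(outer(alphabet, alphabet, dipeptide_name, gap = gap)))
  ch <- strsplit(reduced_seq, "")[[1]]
  L <- length(ch)
  counts <- stats::setNames(integer(length(nm)), nm)
  if (L <= gap + 1L) return(counts)
  first <- factor(ch[seq_len(L - gap - 1L)], levels = alphabet)
  second <- factor(ch[(gap + 2L):L], levels = alphabet)
  tab <- table(first, second)
  counts[] <- as.integer(as.vector(t(tab)))
  counts
}

#' Frequencies of lambda-gap dipeptides
#'
#' Each count is divided by the total number of lambda-gap positions
#' (the sum of all counts at that lambda), so frequencies at a given lambda
#' sum to 1. For degenerate sequences with no lambda-gap position all
#' frequencies are 0.
#'
#' @inheritParams gapped_dipeptide_counts
#' @return Named numeric vector of frequencies.
#' @export
gapped_dipeptide_frequencies <- function(reduced_seq, gap = 0L,
                                         alphabet = scheme_alphabet(default_scheme())) {
  counts <- gapped_dipeptide_counts(reduced_seq, gap, alphabet)
  total <- sum(counts)
  if (total == 0L) return(counts * 0)
  counts / total
}

#' Default physicochemical property table
#'
#' Three classical per-residue scales: Kyte-Doolittle hydrophobicity,
#' Hopp-Woods hydrophilicity, and side-chain mass. Columns are standardized
#' to mean 0 and unit variance over the 20 amino acids, so auto- and
#' cross-covariances computed from different scales are commensurable.
#'
#' @return Numeric matrix, 20 rows (amino acids) by 3 standardized columns.
#' @export
default_property_table <- function() {
  hydrophobicity <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                      G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                      M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                      S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  hydrophilicity <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                      G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                      M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                      S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  sidechain_mass <- c(A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0,
                      G = 1.0, H = 82.0, I = 57.0, K = 73.0, L = 57.0,
                      M = 75.0, N = 58.0, P = 42.0, Q = 72.0, R = 101.0,
                      S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0)
  raw <- cbind(hydrophobicity = hydrophobicity[AA20],
               hydrophilicity = hydrophilicity[AA20],
               sidechain_mass = sidechain_mass[AA20])
  std <- scale(raw)
  dimnames(std) <- dimnames(raw)
  attr(std, "scaled:center") <- NULL
  attr(std, "scaled:scale") <- NULL
  std
}

#' Read a property table from TSV
#'
#' Rows are amino acids (first column holds the one-letter code), remaining
#' columns are numeric property scales; columns are standardized to mean 0,
#' unit variance over the 20 letters.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Standardized numeric matrix, 20 rows.
#' @export
read_property_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rn <- toupper(tab[[1]])
  if (!setequal(rn, AA20)) {
    stop("property table must have exactly the 20 standard amino acids as rows")
  }
  raw <- as.matrix(tab[, -1, drop = FALSE])
  rownames(raw) <- rn
  raw <- raw[AA20, , drop = FALSE]
  std <- scale(raw)
  dimnames(std) <- dimnames(raw)
  attr(std, "scaled:center") <- NULL
  attr(std, "scaled:scale") <- NULL
  std
}

#' Auto-cross covariance (ACC) descriptors of a sequence
#'
#' For property j with per-residue profile P_j and sequence mean Pbar_j, the
#' auto covariance at lag g is
#' `AC(j, g) = (1/(L-g)) * sum_i (P_j(i) - Pbar_j) (P_j(i+g) - Pbar_j)`,
#' and for an ordered property pair j != k the cross covariance is
#' `CC(j, k, g) = (1/(L-g)) * sum_i (P_j(i) - Pbar_j) (P_k(i+g) - Pbar_k)`.
#' With p properties and lags 1..maxlag the descriptor has
#' `p*maxlag + p*(p-1)*maxlag` entries, AC block first (property-major,
#' lag-minor), then CC (pair-major, lag-minor).
#'
#' @param seq A single amino-acid sequence (unreduced).
#' @param props Property matrix as from [default_property_table()].
#' @param maxlag Largest lag g; the sequence must be longer than `maxlag`.
#' @return Named numeric vector of AC then CC values.
#' @export
acc_features <- function(seq, props = default_property_table(), maxlag = 2L) {
  stopifnot(length(seq) == 1L, maxlag >= 1L)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  if (L <= maxlag) stop("sequence length must exceed maxlag")
  if (any(!ch %in% rownames(props))) stop("sequence letter missing from property table")
  P <- props[ch, , drop = FALSE]
  C <- sweep(P, 2L, colMeans(P))
  p <- ncol(props)
  pn <- colnames(props)
  out <- numeric(0)
  for (j in seq_len(p)) {
    for (g in seq_len(maxlag)) {
      v <- sum(C[seq_len(L - g), j] * C[(g + 1L):L, j]) / (L - g)
      out <- c(out, stats::setNames(v, sprintf("AC_%s_lag%d", pn[j], g)))
    }
  }
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      if (k == j) next
      for (g in seq_len(maxlag)) {
        v <- sum(C[seq_len(L - g), j] * C[(g + 1L):L, k]) / (L - g)
        out <- c(out, stats::setNames(v, sprintf("CC_%s_%s_lag%d", pn[j], pn[k], g)))
      }
    }
  }
  out
}

#' Assemble the feature matrix for a set of records
#'
#' Columns are, in order, all dipeptide features for each gap in `gaps`
#' (ordered letter pairs, first letter major, in scheme-alphabet order),
#' followed by the ACC block when `props` is supplied. With the default
#' five-letter scheme and gaps 0..2 this gives 25+25+25 = 75 dipeptide
#' columns plus 18 ACC columns, 93 in total.
#'
#' @param records Data frame with columns `id`, `seq` and optionally `label`.
#' @param scheme Reduction scheme (see [as_scheme()]).
#' @param gaps Integer vector of lambda values.
#' @param props Property matrix for ACC, or `NULL` to omit the ACC block.
#' @param maxlag Largest ACC lag.
#' @param type `"frequency"` (normalized, the model's representation) or
#'   `"count"` (raw integers) for the dipeptide block.
#' @return A `feature_matrix`: list with `values` (samples x features numeric
#'   matrix, rownames = ids) and `labels` (factor with levels negative,
#'   positive, or `NULL`).
#' @export
extract_feature_matrix <- function(records, scheme = default_scheme(),
                                   gaps = 0:2,
                                   props = default_property_table(),
                                   maxlag = 2L,
                                   type = c("frequency", "count")) {
  type <- match.arg(type)
  stopifnot(nrow(records) > 0L)
  scheme <- as_scheme(scheme)
  alphabet <- scheme_alphabet(scheme)
  reduced <- reduce_sequence(records$seq, scheme)
  dip_fun <- if (type == "frequency") gapped_dipeptide_frequencies else gapped_dipeptide_counts
  rows <- lapply(seq_len(nrow(records)), function(i) {
    dip <- unlist(lapply(gaps, function(g) dip_fun(reduced[i], g, alphabet)))
    if (is.null(props)) dip else c(dip, acc_features(records$seq[i], props, maxlag))
  })
  values <- do.call(rbind, rows)
  rownames(values) <- records$id
  labels <- NULL
  if ("label" %in% names(records) && !all(is.na(records$label))) {
    labels <- factor(records$label, levels = c("negative", "positive"))
    if (anyNA(labels)) stop("labels must be 'positive' or 'negative' for all records")
  }
  feature_matrix(values, labels)
}

#' Construct a feature matrix object
#'
#' @param values Numeric samples x features matrix with unique column names.
#' @param labels Optional factor (levels negative, positive) of length
#'   `nrow(values)`.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !anyDuplicated(colnames(values)), !anyNA(values))
  if (!is.null(labels)) {
    labels <- factor(labels, levels = c("negative", "positive"))
    stopifnot(length(labels) == nrow(values), !anyNA(labels))
  }
  structure(list(values = values, labels = labels), class = "feature_matrix")
}

#' Restrict a feature matrix to named features
#'
#' @param fm A `feature_matrix`.
#' @param features Character vector of feature names (kept in given order).
#' @return A `feature_matrix` with only those columns.
#' @export
fm_subset <- function(fm, features) {
  missing <- setdiff(features, colnames(fm$values))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  feature_matrix(fm$values[, features, drop = FALSE], fm$labels)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) " (unlabeled)"
              else sprintf(" (%d positive / %d negative)",
                           sum(x$labels == "positive"), sum(x$labels == "negative"))))
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' First column `id`, then `label` when present, then named feature columns,
#' with a header row.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- data.frame(id = rownames(fm$values), stringsAsFactors = FALSE)
  if (!is.null(fm$labels)) df$label <- as.character(fm$labels)
  df <- cbind(df, as.data.frame(fm$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from TSV
#'
#' @param path Path written by [write_feature_tsv()] (or compatible: first
#'   column id, optional second column label, then numeric feature columns).
#' @return A `feature_matrix`.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  labels <- NULL
  if (names(df)[1] == "label") {
    labels <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  values <- as.matrix(df)
  rownames(values) <- ids
  feature_matrix(values, labels)
}
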