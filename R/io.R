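#' Canonicalize an amino-acid sequence
#'
#' Uppercases, strips alignment gaps (`-`, `.`) and stop/terminator `*`
#' characters, maps the ambiguity codes B, Z, U, J, O to D, E, C, L, K, and
#' drops X or any other non-standard letter with a warning. The result is a
#' string over the 20 standard one-letter codes.
#'
#' @param seq Character vector of raw sequences.
#' @return Character vector of canonicalized sequences.
#' @export
#' @examples
#' canonicalize_sequence("mkv*")   # "MKV"
#' canonicalize_sequence("MK-VB")  # "MKVD"
canonicalize_sequence <- function(seq) {
  stopifnot(is.character(seq))
  out <- toupper(seq)
  out <- gsub("[-.*]", "", out, perl = TRUE)
  for (bad in names(AA_SUBSTITUTIONS)) {
    out <- gsub(bad, AA_SUBSTITUTIONS[[bad]], out, fixed = TRUE)
  }
  dropped <- vapply(out, function(s) {
    sum(!strsplit(s, "")[[1]] %in% AA20)
  }, integer(1), USE.NAMES = FALSE)
  if (any(dropped > 0L)) {
    warning(sprintf(
      "dropped %d non-standard residue(s) (e.g. X) from %d sequence(s)",
      sum(dropped), sum(dropped > 0L)
    ))
    out <- vapply(out, function(s) {
      ch <- strsplit(s, "")[[1]]
      paste(ch[ch %in% AA20], collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are canonicalized with [canonicalize_sequence()]; record ids are
#' the FASTA headers up to the first whitespace and must be unique. Records
#' retain file order.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param label Optional class tag (`"positive"` or `"negative"`) attached to
#'   every record in the file; `NA` when labels come from a table instead
#'   (see [apply_labels()]).
#' @return A data frame with columns `id`, `seq`, `label`.
#' @export
read_fasta <- function(path, label = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: sequence data before first header at line %d of %s",
                 first, path))
  }
  sset <- Biostrings::readBStringSet(path)
  if (length(sset) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(sset))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- canonicalize_sequence(as.character(sset))
  if (any(!nzchar(seqs))) {
    stop("sequence empty after canonicalization: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), label = label,
             stringsAsFactors = FALSE)
}

#' Read a labeled two-class dataset from two FASTA files
#'
#' @param pos_path FASTA file of positive-class (immunoglobulin) sequences.
#' @param neg_path FASTA file of negative-class sequences.
#' @return A data frame with columns `id`, `seq`, `label`; positives first.
#' @export
read_labeled_fasta <- function(pos_path, neg_path) {
  recs <- rbind(read_fasta(pos_path, label = "positive"),
                read_fasta(neg_path, label = "negative"))
  if (anyDuplicated(recs$id)) {
    stop("duplicate ids across classes: ",
         paste(unique(recs$id[duplicated(recs$id)]), collapse = ", "))
  }
  recs
}

#' Attach class labels from a two-column TSV
#'
#' The table has columns id and label (no header row required); FASTA headers
#' are never parsed for labels.
#'
#' @param records Data frame from [read_fasta()].
#' @param path Path to a tab-separated file with columns id, label.
#' @return `records` with the `label` column filled in.
#' @export
apply_labels <- function(records, path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("id", "label"))
  if (nrow(tab) > 0 && identical(tolower(tab$id[1]), "id")) tab <- tab[-1L, ]
  bad <- setdiff(tab$label, c("positive", "negative"))
  if (length(bad)) stop("unknown labels in ", path, ": ", paste(bad, collapse = ", "))
  idx <- match(records$id, tab$id)
  if (anyNA(idx)) {
    stop("no label for id(s): ", paste(records$id[is.na(idx)], collapse = ", "))
  }
  records$label <- tab$label[idx]
  records
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  sset <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(sset, path, width = width)
  invisible(path)
}
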