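#' Reduced amino acid cluster (RAAC) schemes
#'
#' A reduction scheme partitions the 20 standard amino acids into clusters,
#' each written by a single representative letter. Reducing a sequence
#' replaces every residue by its cluster representative, simplifying the
#' sequence while retaining physicochemical signal.
#'
#' @param spec Dash-delimited cluster string, e.g.
#'   `"GPHNDERQKAST-FY-VMIL-C-W"`. Each cluster's representative defaults to
#'   its first letter; an explicit representative may be given as
#'   `"cluster:rep"`.
#' @param name Optional scheme name.
#' @return An object of class `raac_scheme` with elements `clusters` (list of
#'   character vectors), `representatives` (character vector) and `name`.
#' @export
#' @examples
#' sch <- parse_scheme("GPHNDERQKAST-FY-VMIL-C-W")
#' reduce_sequence("FY", sch)  # "FF"
parse_scheme <- function(spec, name = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty scheme specification")
  clusters <- vector("list", length(parts))
  reps <- character(length(parts))
  for (i in seq_along(parts)) {
    piece <- strsplit(parts[i], ":", fixed = TRUE)[[1]]
    members <- strsplit(toupper(piece[1]), "")[[1]]
    rep_i <- if (length(piece) > 1L) toupper(piece[2]) else members[1]
    bad <- setdiff(members, AA20)
    if (length(bad)) {
      stop("non-amino-acid character in scheme: ", paste(bad, collapse = ", "))
    }
    if (anyDuplicated(members)) {
      stop("duplicate letter within cluster: ",
           paste(unique(members[duplicated(members)]), collapse = ", "))
    }
    if (!rep_i %in% members) {
      stop("representative ", rep_i, " is not a member of its cluster ", piece[1])
    }
    clusters[[i]] <- members
    reps[i] <- rep_i
  }
  all_members <- unlist(clusters)
  if (anyDuplicated(all_members)) {
    stop("duplicate letter across clusters: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  missing <- setdiff(AA20, all_members)
  if (length(missing)) {
    stop("scheme does not cover: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reps)) {
    stop("duplicate representatives: ",
         paste(unique(reps[duplicated(reps)]), collapse = ", "))
  }
  structure(list(clusters = clusters, representatives = reps,
                 name = if (is.null(name)) spec else name),
            class = "raac_scheme")
}

#' The built-in five-letter immunoglobulin scheme
#'
#' The five clusters GPHNDERQKAST, FY, VMIL, C, W with representatives
#' G, F, V, C, W. Under this scheme every polar/small/charged residue is
#' written G, the aromatic pair F/Y is written F, the branched aliphatics
#' V/M/I/L are written V, and the rare residues C and W keep their own
#' letters.
#'
#' @return An `raac_scheme` with 5 clusters, named `"ig5"`.
#' @export
#' @examples
#' default_scheme()
default_scheme <- function() {
  parse_scheme("GPHNDERQKAST-FY-VMIL-C-W", name = "ig5")
}

#' Resolve a scheme argument
#'
#' Accepts an `raac_scheme`, the built-in name `"ig5"`, or a dash-delimited
#' cluster string.
#' @param scheme Scheme object, name, or specification string.
#' @return An `raac_scheme`.
#' @export
as_scheme <- function(scheme) {
  if (inherits(scheme, "raac_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) {
    if (identical(scheme, "ig5")) return(default_scheme())
    return(parse_scheme(scheme))
  }
  stop("cannot interpret scheme argument")
}

#' Alphabet of a reduction scheme
#'
#' @param scheme An `raac_scheme`.
#' @return Character vector of cluster representatives, in cluster order.
#' @export
scheme_alphabet <- function(scheme) {
  as_scheme(scheme)$representatives
}

#' Reduce amino-acid sequences onto a scheme's representative alphabet
#'
#' Character `i` of the output is the representative of the cluster
#' containing character `i` of the input: length is always preserved.
#'
#' @param seq Character vector of sequences over the 20 standard letters.
#' @param scheme An `raac_scheme` (or anything [as_scheme()] accepts).
#' @return Character vector of reduced sequences.
#' @export
#' @examples
#' reduce_sequence("ISNVTREDAGTYTC", default_scheme())
reduce_sequence <- function(seq, scheme = default_scheme()) {
  scheme <- as_scheme(scheme)
  from <- unlist(scheme$clusters)
  to <- rep(scheme$representatives, lengths(scheme$clusters))
  covered <- vapply(seq, function(s) {
    all(strsplit(s, "")[[1]] %in% from)
  }, logical(1), USE.NAMES = FALSE)
  if (!all(covered)) {
    stop("sequence contains letters outside the scheme; canonicalize first")
  }
  chartr(paste(from, collapse = ""), paste(to, collapse = ""), seq)
}

#' @export
format.raac_scheme <- function(x, ...) {
  paste(vapply(seq_along(x$clusters), function(i) {
    paste0(paste(x$clusters[[i]], collapse = ""), ":", x$representatives[i])
  }, character(1)), collapse = "-")
}

#' @export
print.raac_scheme <- function(x, ...) {
  cat(sprintf("RAAC scheme '%s' (%d clusters): %s\n",
              x$name, length(x$clusters), format(x)))
  invisible(x)
}
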