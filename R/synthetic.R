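#' Swiss-Prot-like average amino-acid composition
#'
#' Average residue frequencies of well-annotated protein sequences,
#' normalized to sum to 1. Used as the default background so synthetic
#' sequences carry realistic residue statistics — in particular the rarity
#' of cysteine and tryptophan, which is what makes C-anchored reduced
#' dipeptides informative rather than ubiquitous.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
background_composition <- function() {
  pct <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86,
           G = 7.08, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
           M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
           S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92)
  pct[AA20] / sum(pct)
}

#' Configuration of the synthetic dataset generator
#'
#' The generator emulates a two-class protein dataset in which the positive
#' class shares a conserved motif: positives receive one motif insertion at
#' a uniform random position with probability `motif_prob`, and negatives
#' receive extra G-x-C contexts (decoys) that enrich the confounding G*C
#' reduced dipeptide by the factor `decoy_gc_boost` over its background
#' expectation. Class sizes default to 109 positives and 119 negatives.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Integer `(min, max)` sequence lengths; `min` must be
#'   at least the motif length.
#' @param background Amino-acid composition (20 probabilities summing to 1).
#' @param motif Motif string inserted into positives.
#' @param motif_prob Probability a positive receives one motif insertion.
#' @param decoy_gc_boost Multiplicative enrichment of G-gap-C contexts in
#'   negatives (1 = no enrichment).
#' @param seed Integer seed; generation is fully determined by it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_pos = 109L, n_neg = 119L,
                             length_range = c(100L, 500L),
                             background = background_composition(),
                             motif = "ISNVTREDAGTYTC",
                             motif_prob = 0.98,
                             decoy_gc_boost = 3.0,
                             seed = 7L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            length(length_range) == 2L, length_range[1] <= length_range[2],
            motif_prob >= 0, motif_prob <= 1, decoy_gc_boost >= 1)
  if (!setequal(names(background), AA20)) {
    stop("background composition must name exactly the 20 standard amino acids")
  }
  background <- background[AA20]
  if (any(background < 0) || abs(sum(background) - 1) > 1e-9) {
    stop("background composition must be non-negative and sum to 1")
  }
  if (length_range[1] < nchar(motif)) {
    stop("minimum length must be at least the motif length (",
         nchar(motif), ")")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 background = background, motif = motif,
                 motif_prob = motif_prob, decoy_gc_boost = decoy_gc_boost,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a labeled synthetic dataset
#'
#' Deterministic given `config$seed`. Positives are background sequences
#' with the motif overwriting a uniform random window (with probability
#' `motif_prob`); negatives are background sequences with a Poisson number
#' of extra G-x-C decoy contexts, calibrated so their expected G*C
#' (lambda = 1) count is `decoy_gc_boost` times the background expectation.
#' Decoy first letters are drawn from the scheme's G-cluster at background
#' proportions, so decoys stay composition-plausible.
#'
#' @param config A `generator_config`.
#' @param scheme Reduction scheme used to define the decoy G-cluster.
#' @return List with `records` (data frame `id`, `seq`, `label`),
#'   `manifest` (data frame `id`, `motif_start`, one row per actual motif
#'   insertion) and `config`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_pos = 5, n_neg = 5, seed = 1))
#' nrow(ds$records)  # 10
generate_dataset <- function(config = generator_config(),
                             scheme = default_scheme()) {
  stopifnot(inherits(config, "generator_config"))
  scheme <- as_scheme(scheme)
  bg <- config$background
  motif_ch <- strsplit(config$motif, "")[[1]]
  k <- length(motif_ch)
  g_cluster <- scheme$clusters[[match("G", scheme$representatives)]]
  p_g <- sum(bg[g_cluster])
  p_c <- bg[["C"]]
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  lmin <- config$length_range[1]
  lmax <- config$length_range[2]
  random_sequence <- function(L) sample(AA20, L, replace = TRUE, prob = bg)
  ids <- c(sprintf("pos_%03d", seq_len(config$n_pos)),
           sprintf("neg_%03d", seq_len(config$n_neg)))
  seqs <- character(config$n_pos + config$n_neg)
  manifest <- data.frame(id = character(0), motif_start = integer(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(config$n_pos)) {
    L <- sample(lmin:lmax, 1L)
    s <- random_sequence(L)
    if (stats::runif(1) < config$motif_prob) {
      start <- sample.int(L - k + 1L, 1L)
      s[start:(start + k - 1L)] <- motif_ch
      manifest <- rbind(manifest,
                        data.frame(id = ids[i], motif_start = start,
                                   stringsAsFactors = FALSE))
    }
    seqs[i] <- paste(s, collapse = "")
  }
  for (i in seq_len(config$n_neg)) {
    L <- sample(lmin:lmax, 1L)
    s <- random_sequence(L)
    n_decoy <- stats::rpois(1L, (config$decoy_gc_boost - 1) * p_g * p_c * (L - 2L))
    if (n_decoy > 0L) {
      starts <- sample.int(L - 2L, n_decoy, replace = TRUE)
      s[starts] <- sample(g_cluster, n_decoy, replace = TRUE,
                          prob = bg[g_cluster] / p_g)
      s[starts + 2L] <- "C"
    }
    seqs[config$n_pos + i] <- paste(s, collapse = "")
  }
  records <- data.frame(id = ids, seq = seqs,
                        label = rep(c("positive", "negative"),
                                    c(config$n_pos, config$n_neg)),
                        stringsAsFactors = FALSE)
  list(records = records, manifest = manifest, config = config)
}

#' Write a generated dataset to FASTA plus manifest
#'
#' @param dataset Result of [generate_dataset()].
#' @param pos_path,neg_path Output FASTA paths per class.
#' @param manifest_path Optional TSV path recording motif insertions.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, pos_path, neg_path, manifest_path = NULL) {
  recs <- dataset$records
  write_fasta(recs[recs$label == "positive", ], pos_path)
  write_fasta(recs[recs$label == "negative", ], neg_path)
  if (!is.null(manifest_path)) {
    utils::write.table(dataset$manifest, manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(pos_path, neg_path, manifest_path))
}
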