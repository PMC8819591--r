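# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

oracle_gap_counts <- function(seq, gap, alphabet) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  counts <- matrix(0L, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  if (L > gap + 1) {
    for (i in 1:(L - gap - 1)) {
      counts[ch[i], ch[i + gap + 1]] <- counts[ch[i], ch[i + gap + 1]] + 1L
    }
  }
  out <- integer(0)
  for (a in alphabet) for (b in alphabet) {
    out <- c(out, stats::setNames(counts[a, b],
                                  paste0(a, strrep("*", gap), b)))
  }
  out
}

oracle_acc <- function(seq, props, maxlag) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  p <- ncol(props)
  out <- numeric(0)
  prof <- props[ch, , drop = FALSE]
  means <- colMeans(prof)
  for (j in 1:p) for (g in 1:maxlag) {
    s <- 0
    for (i in 1:(L - g)) {
      s <- s + (prof[i, j] - means[j]) * (prof[i + g, j] - means[j])
    }
    out <- c(out, s / (L - g))
  }
  for (j in 1:p) for (k in 1:p) {
    if (k == j) next
    for (g in 1:maxlag) {
      s <- 0
      for (i in 1:(L - g)) {
        s <- s + (prof[i, j] - means[j]) * (prof[i + g, k] - means[k])
      }
      out <- c(out, s / (L - g))
    }
  }
  out
}

# Textbook Pearson correlation, written out.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

oracle_mrmd_scores <- function(values, y01, weights = c(1, 1),
                               metric = "cosine") {
  p <- ncol(values)
  n <- nrow(values)
  Z <- values
  for (j in 1:p) {
    m <- sum(values[, j]) / n
    s <- sqrt(sum((values[, j] - m)^2) / (n - 1))
    Z[, j] <- if (s == 0) 0 else (values[, j] - m) / s
  }
  rel <- numeric(p)
  for (j in 1:p) {
    r <- oracle_pearson(values[, j], y01)
    rel[j] <- if (is.na(r)) 0 else abs(r)
  }
  dst <- numeric(p)
  if (p >= 2) {
    for (j in 1:p) {
      total <- 0
      for (k in setdiff(1:p, j)) {
        total <- total + switch(metric,
          euclidean = sqrt(sum((Z[, j] - Z[, k])^2)),
          cosine = {
            nj <- sqrt(sum(Z[, j]^2)); nk <- sqrt(sum(Z[, k]^2))
            if (nj == 0 || nk == 0) 1 else 1 - sum(Z[, j] * Z[, k]) / (nj * nk)
          },
          tanimoto = {
            d <- sum(Z[, j]^2) + sum(Z[, k]^2) - sum(Z[, j] * Z[, k])
            if (d == 0) 0 else 1 - sum(Z[, j] * Z[, k]) / d
          })
      }
      dst[j] <- total / (p - 1)
    }
  }
  weights[1] * rel + weights[2] * dst
}

# Exhaustive best gain-ratio root split: every feature, every midpoint
# between adjacent distinct sorted values, same tie rule as the trainer
# (lower feature index, then lower threshold).
oracle_root_split <- function(values, y01, min_leaf = 2L) {
  n <- length(y01)
  ent <- function(pos, tot) {
    if (tot == 0) return(0)
    pr <- pos / tot
    h <- 0
    if (pr > 0) h <- h - pr * log2(pr)
    if (pr < 1) h <- h - (1 - pr) * log2(1 - pr)
    h
  }
  hp <- ent(sum(y01), n)
  best <- NULL
  for (f in seq_len(ncol(values))) {
    v <- sort(unique(values[, f]))
    if (length(v) < 2) next
    for (i in 1:(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      left <- values[, f] <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      gain <- hp - (nl * ent(sum(y01[left]), nl) +
                    (n - nl) * ent(sum(y01[!left]), n - nl)) / n
      if (gain <= 1e-12) next
      si <- ent(nl, n)
      gr <- gain / si
      if (is.null(best) || gr > best$gain_ratio + 1e-12) {
        best <- list(feature = f, threshold = thr, gain_ratio = gr)
      }
    }
  }
  best
}

oracle_substring_count <- function(seq, motif) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (L < k) return(0L)
  hits <- 0L
  for (i in 1:(L - k + 1)) {
    if (substr(seq, i, i + k - 1) == motif) hits <- hits + 1L
  }
  hits
}

random_aa_seq <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                            "H", "I", "K", "L", "M", "N",
                                            "P", "Q", "R", "S", "T", "V",
                                            "W", "Y")) {
  if (len == 0) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Small labeled feature matrix for classifier tests.
make_fm <- function(values, labels) {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  feature_matrix(values, factor(ifelse(labels == 1, "positive", "negative"),
                                levels = c("negative", "positive")))
}

tree_depth_for_test <- function(tree) {
  depth_of <- function(node) {
    if (node$type == "leaf") return(0L)
    1L + max(depth_of(node$left), depth_of(node$right))
  }
  depth_of(tree$root)
}
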