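test_that("gapped dipeptide counts match the worked reduced-motif example", {
  counts <- gapped_dipeptide_counts("VGGVGGGGGGGFGC", gap = 1)
  expect_equal(counts[["F*C"]], 1L)
  expect_equal(counts[["G*C"]], 0L)
  expect_equal(counts[["G*G"]], 7L)
  expect_equal(sum(counts), 14L - 1L - 1L)
  expect_identical(counts, oracle_gap_counts("VGGVGGGGGGGFGC", 1,
                                             c("G", "F", "V", "C", "W")))
})

test_that("degenerate lengths give zero counts and zero frequencies", {
  expect_equal(sum(gapped_dipeptide_counts("FC", gap = 1)), 0L)
  z <- gapped_dipeptide_frequencies("GG", gap = 2)
  expect_true(all(z == 0))
  direct <- gapped_dipeptide_counts("GGG", gap = 0)
  expect_equal(direct[["GG"]], 2L)
  expect_equal(sum(direct), 2L)
})

test_that("frequencies are counts over the per-lambda total and sum to one", {
  f <- gapped_dipeptide_frequencies("VGGVGGGGGGGFGC", gap = 1)
  expect_equal(f[["F*C"]], 1 / 12)
  withr::with_seed(21, {
    for (i in 1:60) {
      gap <- sample(0:3, 1)
      s <- random_aa_seq(sample(0:30, 1), c("G", "F", "V", "C", "W"))
      s_red <- s
      f <- gapped_dipeptide_frequencies(s_red, gap)
      expect_true(isTRUE(all.equal(sum(f), 1)) || all(f == 0))
    }
  })
})

test_that("counts equal the brute-force double-loop oracle on random inputs", {
  withr::with_seed(31, {
    for (i in 1:200) {
      asz <- sample(1:20, 1)
      alpha <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), asz)
      s <- random_aa_seq(sample(0:50, 1), alpha)
      gap <- sample(0:3, 1)
      expect_identical(gapped_dipeptide_counts(s, gap, alpha),
                       oracle_gap_counts(s, gap, alpha))
    }
  })
})

test_that("ACC matches the hand-worked single-property example", {
  props <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "C"), "toy"))
  expect_equal(acc_features("ACA", props, maxlag = 1)[["AC_toy_lag1"]], -8 / 9)
})

test_that("ACC of a homopolymer is identically zero and defaults give 18 values", {
  v <- acc_features(strrep("A", 25))
  expect_length(v, 18L)
  expect_true(all(abs(v) < 1e-12))
  expect_error(acc_features("AC", maxlag = 2), "exceed maxlag")
})

test_that("ACC equals the brute-force covariance oracle on random sequences", {
  props <- default_property_table()
  withr::with_seed(41, {
    for (i in 1:100) {
      s <- random_aa_seq(sample(4:30, 1))
      maxlag <- sample(1:3, 1)
      expect_equal(unname(acc_features(s, props, maxlag)),
                   unname(oracle_acc(s, props, maxlag)),
                   tolerance = 1e-10)
    }
  })
})

test_that("feature matrix has the documented column layout", {
  recs <- data.frame(id = c("a", "b"),
                     seq = c(strrep("MKVC", 30), strrep("WYA", 40)),
                     label = c("positive", "negative"),
                     stringsAsFactors = FALSE)
  fm <- extract_feature_matrix(recs)
  expect_equal(dim(fm$values), c(2L, 93L))
  nm <- colnames(fm$values)
  expect_equal(sum(grepl("^[A-Z]\\**[A-Z]$", nm)), 75L)
  expect_equal(sum(grepl("^(AC|CC)_", nm)), 18L)
  # dipeptide block first: lambda 0 then 1 then 2, first letter major
  expect_equal(nm[1], "GG")
  expect_equal(nm[26], "G*G")
  expect_equal(nm[51], "G**G")
  expect_true(all(grepl("^AC_", nm[76:81])))
  expect_true(all(grepl("^CC_", nm[82:93])))
})

test_that("column count follows |alphabet|^2 * |gaps| + p*maxlag + p*(p-1)*maxlag", {
  recs <- data.frame(id = c("a", "b"), seq = c(strrep("MKVC", 30), strrep("WYAC", 25)),
                     stringsAsFactors = FALSE)
  for (cfg in list(list(scheme = "FY-ACDEGHIKLMNPQRSTVW", gaps = 0:1, maxlag = 3),
                   list(scheme = "ACDEFGHIKLMNPQRSTVWY", gaps = 0L, maxlag = 1))) {
    sch <- parse_scheme(cfg$scheme)
    a <- length(scheme_alphabet(sch))
    props <- default_property_table()
    p <- ncol(props)
    fm <- extract_feature_matrix(recs, sch, gaps = cfg$gaps, props = props,
                                 maxlag = cfg$maxlag)
    expect_equal(ncol(fm$values),
                 a^2 * length(cfg$gaps) + p * cfg$maxlag + p * (p - 1) * cfg$maxlag)
  }
})

test_that("degenerate one-cluster scheme with no ACC gives a single all-ones column", {
  recs <- data.frame(id = c("a", "b"), seq = c("MKVC", "WWYA"),
                     stringsAsFactors = FALSE)
  fm <- extract_feature_matrix(recs, parse_scheme("ACDEFGHIKLMNPQRSTVWY"),
                               gaps = 0L, props = NULL)
  expect_equal(dim(fm$values), c(2L, 1L))
  expect_true(all(fm$values == 1))
})

test_that("dipeptide name aliases parse to the canonical infix form", {
  expect_equal(parse_dipeptide("FC*")$canonical, "F*C")
  expect_equal(parse_dipeptide("GC**")$canonical, "G**C")
  expect_equal(parse_dipeptide("F*C")$gap, 1L)
  expect_equal(parse_dipeptide("GC")$gap, 0L)
  expect_error(parse_dipeptide("F**"), "cannot parse")
})

test_that("feature matrix TSV round-trips values and labels", {
  recs <- data.frame(id = c("a", "b"),
                     seq = c(strrep("MKVC", 30), strrep("WYA", 40)),
                     label = c("positive", "negative"), stringsAsFactors = FALSE)
  fm <- extract_feature_matrix(recs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fm, f)
  back <- read_feature_tsv(f)
  expect_equal(colnames(back$values), colnames(fm$values))
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$labels, fm$labels)
})
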