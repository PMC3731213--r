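test_that("LLR scoring matches hand arithmetic and identity cases", {
  # uniform PWM, uniform background: every k-mer scores 0
  u <- uniform_pwm(4)
  for (k in c("ACGT", "AAAA", "TGCA")) {
    expect_equal(llr_score(u, k), 0)
  }
  # 1-column PWM p = (0.7, 0.1, 0.1, 0.1), no pseudocount: ln(0.7/0.25)
  p <- pwm(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 4), name = "one",
           pseudocount = 0)
  expect_equal(llr_score(p, "A"), log(0.7 / 0.25), tolerance = 1e-12)
  expect_equal(llr_score(p, "C"), log(0.1 / 0.25), tolerance = 1e-12)
  # consensus k-mer scores llr_max
  m <- fix_primary()
  expect_equal(llr_score(m, consensus_seq(m)), llr_max(m), tolerance = 1e-12)
  # errors: length mismatch, non-ACGT
  expect_error(llr_score(m, "ACGT"), "length")
  expect_error(llr_score(p, "N"), "non-ACGT")
})

test_that("minus-strand LLR equals plus-strand LLR of the reverse complement", {
  m <- fix_primary()
  set.seed(5)
  for (i in 1:20) {
    kmer <- paste(sample(c("A", "C", "G", "T"), pwm_length(m),
                         replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
    expect_equal(llr_score(m, kmer, "-"), llr_score(m, rc, "+"),
                 tolerance = 1e-12)
  }
})

test_that("scan_sites finds planted sites and respects thresholds", {
  m <- fix_primary()
  seq <- paste0(strrep("A", 40), consensus_seq(m), strrep("T", 40))
  hits <- scan_sites(m, seq, min_rel_affinity = 0.5)
  # non-palindromic high-IC motif: exactly the planted site
  strong <- hits[hits$rel_affinity > 0.99, ]
  expect_equal(nrow(strong), 1)
  expect_equal(strong$start, 40)
  expect_equal(strong$end, 40 + pwm_length(m))
  expect_equal(strong$strand, "+")

  # threshold 0: one site per position per strand
  all_hits <- scan_sites(m, seq, min_rel_affinity = 0)
  expect_equal(nrow(all_hits), 2 * (nchar(seq) - pwm_length(m) + 1))

  # raising the threshold never adds sites, and results are nested
  lo <- scan_sites(m, seq, min_rel_affinity = 0.001)
  hi <- scan_sites(m, seq, min_rel_affinity = 0.1)
  expect_lte(nrow(hi), nrow(lo))
  expect_true(all(paste(hi$start, hi$strand) %in% paste(lo$start, lo$strand)))

  # all-N sequence: no sites
  expect_equal(nrow(scan_sites(m, strrep("N", 100))), 0)
  # N disqualifies overlapping sites only
  seqN <- paste0(strrep("A", 40), consensus_seq(m), "N", consensus_seq(m))
  h <- scan_sites(m, seqN, min_rel_affinity = 0.99)
  expect_true(all(h$start != 41))
})

test_that("shuffle_pwm preserves information content and column multiset", {
  m <- fix_primary()
  ic0 <- oracle_ic(m$probs)
  set.seed(42)
  for (i in 1:100) {
    s <- shuffle_pwm(m)
    expect_equal(oracle_ic(s$probs), ic0, tolerance = 1e-12)
    # multiset of column vectors preserved up to base relabeling:
    # sorted per-column probabilities must match as a multiset
    a <- apply(m$probs, 2, sort)
    b <- apply(s$probs, 2, sort)
    expect_equal(a[, order(a[1, ], a[2, ], a[3, ])],
                 b[, order(b[1, ], b[2, ], b[3, ])],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("information content: identity cases and shuffle invariance", {
  expect_equal(information_content(uniform_pwm(6)), 0, tolerance = 1e-12)
  onehot <- pwm(matrix(c(1, 0, 0, 0), nrow = 4), name = "hot",
                pseudocount = 1e-6)
  expect_equal(information_content(onehot), 2, tolerance = 1e-3)
  m <- fix_secondary()
  set.seed(3)
  expect_equal(information_content(shuffle_pwm(m)), information_content(m),
               tolerance = 1e-12)
})

test_that("exact score-distribution threshold matches enumeration on a short PWM", {
  m <- gen_pwm(5, 6, seed = 9, name = "short")
  alpha <- exp(-7)
  thr <- llr_threshold_pvalue(m, alpha, bin = 0.001)
  # enumerate all 4^5 k-mers under the uniform background
  kmers <- expand.grid(rep(list(c("A", "C", "G", "T")), 5),
                       stringsAsFactors = FALSE)
  scores <- apply(kmers, 1, function(r)
    llr_score(m, paste(r, collapse = "")))
  tail_at <- function(t) mean(scores >= t)
  expect_lte(tail_at(thr), alpha)
  # minimality: the next attainable score below the threshold (beyond the
  # discretization guard band) would exceed alpha
  below <- scores[scores < thr - 0.01]
  expect_gt(tail_at(max(below)), alpha)
})

test_that("MEME round-trip and TSV reading preserve PWMs", {
  m1 <- fix_primary()
  m2 <- fix_secondary()
  path <- tempfile(fileext = ".meme")
  write_meme(list(m1, m2), path)
  # probs on disk are already floored; read back without re-flooring
  back <- read_meme(path, pseudocount = 0)
  expect_equal(names(back), c("prim", "sec"))
  expect_equal(back$prim$probs, m1$probs, tolerance = 1e-4)
  expect_equal(information_content(back$sec), information_content(m2),
               tolerance = 0.01)

  tsv <- tempfile(fileext = ".tsv")
  write.table(cbind(c("A", "C", "G", "T"), m1$probs), tsv, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  m1b <- read_pwm_tsv(tsv, name = "prim", pseudocount = 0)
  expect_equal(m1b$probs, m1$probs, tolerance = 1e-6)
})
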