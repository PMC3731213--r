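chrlen <- c(chrT = 5000)

test_that("track smoothing follows the 50 bp grid-mapping rule", {
  # constant score everywhere: every window scores the constant
  tr <- data.frame(chrom = "chrT", pos = 0:4999, score = 3)
  sm <- smooth_track(tr, chrlen)
  expect_true(all(sm$score == 3))
  expect_true(all(sm$end - sm$start == 500))
  expect_true(all(sm$start %% 50 == 0))

  # single score: exactly the 10 windows covering its grid point score s
  tr1 <- data.frame(chrom = "chrT", pos = 1024, score = 7)  # grid point 1000
  sm1 <- smooth_track(tr1, chrlen)
  hit <- sm1[sm1$score != 0, ]
  expect_equal(nrow(hit), 10)
  expect_true(all(hit$score == 7))
  expect_equal(sort(hit$start), seq(550, 1000, by = 50))

  # empty track: all-zero windows
  sm0 <- smooth_track(tr1[0, ], chrlen)
  expect_true(all(sm0$score == 0))
  # negative positions rejected
  expect_error(smooth_track(data.frame(chrom = "chrT", pos = -5, score = 1),
                            chrlen), "negative")
})

test_that("dataset building selects greedy non-overlapping peaks", {
  set.seed(2)
  genome <- c(chrT = paste(sample(c("A", "C", "G", "T"), 5000,
                                  replace = TRUE), collapse = ""))
  # two disjoint bumps at known grid windows + noise floor
  # bumps end at 1449/3449 so no scores map onto the 1500/3500 grid points
  tr <- data.frame(chrom = "chrT",
                   pos = c(1000:1449, 3000:3449, seq(0, 4999, by = 97)),
                   score = c(rep(10, 450), rep(8, 450),
                             rep(0.1, length(seq(0, 4999, by = 97)))))
  sm <- smooth_track(tr, chrlen)
  ds <- build_dataset(sm, genome, n_peaks = 2, n_nonpeaks = 4, seed = 3,
                      name = "toy")
  peaks <- ds$windows[ds$windows$label == "peak", ]
  # brute force: the best window must cover bump 1, the second bump 2
  expect_equal(peaks$start[1], 1000)
  expect_equal(peaks$start[2], 3000)
  # peaks and non-peaks are disjoint, non-overlapping
  np <- ds$windows[ds$windows$label == "nonpeak", ]
  for (i in seq_len(nrow(np))) {
    expect_false(any(np$start[i] < peaks$end & np$end[i] > peaks$start))
  }
  expect_equal(anyDuplicated(ds$windows$start), 0)
  # sequences match the genome
  expect_equal(ds$seqs[1], substr(genome[["chrT"]], 1001, 1500))

  # seeded non-peak draw is reproducible
  ds2 <- build_dataset(sm, genome, n_peaks = 2, n_nonpeaks = 4, seed = 3)
  expect_identical(ds$windows$start, ds2$windows$start)
  ds3 <- build_dataset(sm, genome, n_peaks = 2, n_nonpeaks = 4, seed = 4)
  expect_false(identical(ds$windows$start, ds3$windows$start))

  # exon exclusion: non-peaks never overlap exons by >= 1 bp
  exons <- data.frame(chrom = "chrT", start = 0, end = 2000)
  dse <- build_dataset(sm, genome, exons = exons, n_peaks = 2, n_nonpeaks = 3,
                       seed = 3)
  npe <- dse$windows[dse$windows$label == "nonpeak", ]
  expect_true(all(npe$start >= 2000))

  # insufficient windows errors with counts
  expect_error(build_dataset(sm, genome, n_peaks = 500, n_nonpeaks = 4),
               "peaks")
})

test_that("primary motif selection picks the generating motif over a decoy", {
  ds <- fix_coop_dataset()
  true_m <- fix_primary()
  set.seed(12)
  decoy <- shuffle_pwm(true_m)
  cfg <- stap_config("single", seed = 1, k = 4)
  # single candidate returned unchanged
  expect_identical(select_primary_motif(list(true_m), ds, cfg)$name, "prim")
  sel <- select_primary_motif(list(decoy, true_m), ds, cfg)
  expect_identical(sel$name, "prim")
  expect_gt(attr(sel, "cc")[2], attr(sel, "cc")[1])
  # two identical candidates: first by input order
  sel2 <- select_primary_motif(list(true_m, true_m), ds, cfg)
  expect_identical(which.max(attr(sel2, "cc")), 1L)
})

test_that("expression ranking z-normalizes stages and filters heterodimers", {
  tfs <- sprintf("tf%02d", 1:20)
  catalog <- setNames(lapply(seq_along(tfs), function(i) {
    gen_pwm(6, 7, seed = i, name = tfs[i])
  }), tfs)
  expr <- gen_expression_table(tfs, stages = c(5, 9), seed = 2,
                               top_tfs = "tf07")
  ranked <- rank_secondary_candidates(expr, stages = c(5, 9), catalog,
                                      top_fraction = 0.10)
  expect_length(ranked, 2)  # ceiling(0.10 * 20)
  expect_identical(ranked[[1]]$name, "tf07")
  # hand z-score oracle on the two-stage ranking
  e <- expr
  e$z <- ave(log1p(e$level), e$stage,
             FUN = function(v) (v - mean(v)) / sd(v))
  sc <- tapply(e$z, e$gene, mean)
  expect_identical(ranked[[2]]$name, names(sort(sc, decreasing = TRUE))[2])
  # fraction 1.0: all candidates, heterodimers excluded
  catalog$tf03$heterodimer <- TRUE
  all_m <- rank_secondary_candidates(expr, c(5, 9), catalog,
                                     top_fraction = 1.0)
  expect_length(all_m, 19)
  expect_false("tf03" %in% vapply(all_m, function(m) m$name, character(1)))
  expect_error(rank_secondary_candidates(expr, stages = 14, catalog),
               "stage")
})

test_that("accessibility attachment thresholds at the requested percentile", {
  ds <- fix_coop_dataset()
  n <- nrow(ds$windows)
  # toy: scores 1..n, percentile 0.9 flags the top 10%
  sm <- data.frame(chrom = ds$windows$chrom, start = ds$windows$start,
                   end = ds$windows$end, score = seq_len(n))
  out <- attach_accessibility(ds, sm)
  expect_equal(sum(out$windows$accessible), ceiling(0.1 * n))
  expect_true(all(which(out$windows$accessible) > n - ceiling(0.1 * n)))
  # all-equal scores: ties at the threshold are accessible
  sm$score <- 5
  out2 <- attach_accessibility(ds, sm)
  expect_true(all(out2$windows$accessible))
  # missing coverage: accessibility 0, counted
  sm3 <- sm[1:10, ]
  out3 <- attach_accessibility(ds, sm3)
  expect_equal(attr(out3, "accessibility_uncovered"), n - 10)
  expect_true(all(out3$windows$accessibility[11:n] == 0))
})
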