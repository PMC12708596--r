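test_that("background sampling honours composition and seed determinism", {
  s <- sample_background(20, 1.0, 9)
  expect_true(grepl("^[GC]{20}$", s))
  s2 <- sample_background(20, 0, 9)
  expect_true(grepl("^[AT]{20}$", s2))

  a <- sample_background(300, 0.5, 7)
  b <- sample_background(300, 0.5, 7)
  expect_identical(a, b)
  expect_false(identical(a, sample_background(300, 0.5, 8)))

  expect_error(sample_background(0, 0.5, 1), "length")
  expect_error(sample_background(10, 1.5, 1), "gc_fraction")
})

test_that("rejection sampling yields motif-free backgrounds", {
  s <- sample_background(200, 0.5, 3,
                         forbid_matches_under = hse_preset("minimal_perfect"))
  rec <- promoter_record("bg", s)
  expect_equal(nrow(oracle_scan(rec, "minimal_perfect")$matches), 0L)
  # an over-constrained request exhausts the attempt cap
  expect_error(
    sample_background(500, 0.5, 3,
                      forbid_matches_under = hse_preset("imperfect_minimal"),
                      max_attempts = 3L),
    "attempts")
})

test_that("planted truths validate their plans against the class envelope", {
  expect_error(planted_truth("r", 0, 3, "GAA_type",
                             expected_class = "imperfect_triple"),
               "realizes class 'canonical'")
  expect_error(planted_truth("r", 0, 2, "GAA_type",
                             sub_plan = data.frame(unit = 1, core_pos = 1,
                                                   base = "G"),
                             expected_class = "imperfect_minimal"),
               "differing from the consensus")
  expect_error(planted_truth("r", 0, 3, "GAA_type", ins_plan = c("A"),
                             expected_class = "imperfect_triple"),
               "one entry per inter-unit gap")
})

test_that("planted canonical elements are recovered at their position", {
  bg <- sample_background(100, 0.5, 5)
  truth <- planted_truth("r", 10, 3, "GAA_type",
                         expected_class = "canonical")
  seq2 <- embed_hse(bg, truth)
  expect_equal(nchar(seq2), 100L)  # overwrite, no internal insertions
  m <- scan_record(promoter_record("r", seq2), "canonical")$matches
  hit <- m[m$start == 10L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$end, 25L)
  expect_equal(hit$substitutions_total, 0L)
  expect_equal(hit$insertions_total, 0L)
})

test_that("substituted plants separate the perfect and imperfect envelopes", {
  bg <- sample_background(80, 0.5, 17,
                          forbid_matches_under = hse_preset("minimal_perfect"))
  truth <- planted_truth("r", 30, 2, "GAA_type",
                         sub_plan = data.frame(unit = 2, core_pos = 1,
                                               base = "A"),
                         expected_class = "imperfect_minimal")
  seq2 <- embed_hse(bg, truth)
  rec <- promoter_record("r", seq2)
  expect_equal(nrow(scan_record(rec, "minimal_perfect")$matches), 0L)
  m <- scan_record(rec, "imperfect_minimal")$matches
  hit <- m[m$start == 30L & m$end == 40L, ]
  expect_equal(hit$substitutions_total, 1L)
  expect_equal(hit$substitution_positions, "u2p1")
})

test_that("gap insertions lengthen the planted element as specified", {
  bg <- strrep("C", 60)
  truth <- planted_truth("r", 5, 3, "TTC_type",
                         ins_plan = c("AG", ""),
                         expected_class = "imperfect_triple")
  seq2 <- embed_hse(bg, truth)
  expect_equal(nchar(seq2), 62L)  # grows by the internal insertions
  m <- scan_record(promoter_record("r", seq2),
                   "imperfect_triple")$matches
  hit <- m[m$start == 5L & m$substitutions_total == 0L, ]
  expect_equal(hit$end - hit$start, 17L)
  expect_equal(hit$insertions_per_gap, "2,0")

  expect_error(embed_hse(strrep("C", 10), truth), "exceeds")
})

test_that("benchmark generation is reproducible bookkeeping", {
  dir1 <- tempfile(); dir2 <- tempfile()
  mix <- c(minimal_perfect = 1.0)
  bm1 <- generate_benchmark(5, 300, 2, mix, seed = 1, out_dir = dir1)
  bm2 <- generate_benchmark(5, 300, 2, mix, seed = 1, out_dir = dir2)
  expect_equal(nrow(bm1$truths), 10L)
  expect_equal(unique(bm1$truths$expected_class), "minimal_perfect")
  expect_identical(readLines(bm1$fasta), readLines(bm2$fasta))
  expect_identical(readLines(bm1$truth_table),
                   readLines(bm2$truth_table))
  expect_equal(nrow(bm1$promoters), 5L)

  expect_error(generate_benchmark(2, 300, 2, c(canonical = 0.5), seed = 1,
                                  out_dir = tempfile()), "sum to 1")
  expect_error(generate_benchmark(2, 300, 2, c(banana = 1), seed = 1,
                                  out_dir = tempfile()), "class labels")
})

test_that("every planted truth is recovered with exact accounting", {
  bm <- generate_benchmark(8, 300, 3, equal_class_mix, seed = 23,
                           out_dir = tempfile())
  scans <- lapply(seq_len(nrow(bm$promoters)), function(i) {
    rec <- bm$promoters[i, , drop = FALSE]
    stats::setNames(lapply(hse_classes, function(cl)
      scan_record(rec, cl)$matches), hse_classes)
  })
  names(scans) <- bm$promoters$record_id
  for (j in seq_len(nrow(bm$truths))) {
    tr <- bm$truths[j, ]
    expect_true(truth_hit(tr, scans[[tr$record_id]][[tr$expected_class]]),
                info = sprintf("truth row %d (%s)", j, tr$record_id))
  }
})
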