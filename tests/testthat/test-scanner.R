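test_that("pentamer unit matching counts core mismatches only", {
  u <- match_unit("AGAAT", 0, "GAA_type")
  expect_equal(u$core_substitutions, 0L)
  expect_equal(u$substituted_core_positions, integer(0))

  u <- match_unit("ACAAT", 0, "GAA_type")
  expect_equal(u$core_substitutions, 1L)
  expect_equal(u$substituted_core_positions, 1L)

  u <- match_unit("TTTCA", 0, "TTC_type")
  expect_equal(u$core_substitutions, 0L)

  # wildcards never contribute; N in a core is a substitution
  expect_equal(match_unit("NGAAN", 0, "GAA_type")$core_substitutions, 0L)
  expect_equal(match_unit("AGNAT", 0, "GAA_type")$core_substitutions, 1L)
  expect_error(match_unit("ACGT", 0, "GAA_type"), "out of range")
  expect_error(match_unit("ACGTACGT", 5, "GAA_type"), "out of range")
})

test_that("constructed elements are found exactly once at the right span", {
  canonical <- scan_record(promoter_record("p1", "AGAACATTCGAGAAT"),
                           "canonical")$matches
  expect_equal(nrow(canonical), 1L)
  expect_equal(canonical$start, 0L)
  expect_equal(canonical$end, 15L)
  expect_equal(canonical$first_unit_orientation, "GAA_type")
  expect_equal(canonical$substitutions_total, 0L)
  expect_equal(canonical$insertions_total, 0L)
  expect_equal(canonical$class, "canonical")

  minimal <- scan_record(promoter_record("p2", "AGAACTTTCG"),
                         "minimal_perfect")$matches
  expect_equal(nrow(minimal), 1L)
  expect_equal(c(minimal$start, minimal$end), c(0L, 10L))
  expect_equal(minimal$first_unit_orientation, "GAA_type")

  background <- promoter_record("p3", strrep("C", 50))
  for (preset in hse_classes) {
    expect_equal(nrow(scan_record(background, preset)$matches), 0L)
  }
})

test_that("seeded random scan equals the brute-force oracle", {
  rec <- random_record(42)
  expect_same_matches(scan_record(rec, "imperfect_minimal")$matches,
                      oracle_scan(rec, "imperfect_minimal")$matches)
  expect_same_matches(scan_record(rec, "imperfect_triple")$matches,
                      oracle_scan(rec, "imperfect_triple")$matches)
})

test_that("match spans satisfy the length identity", {
  rec <- random_record(7)
  for (p in param_grid()) {
    m <- scan_record(rec, p)$matches
    expect_equal(m$end - m$start, 5L * m$n_units + m$insertions_total)
  }
})

test_that("stored substitution accounting is re-derivable from the span", {
  rec <- random_record(13)
  m <- scan_record(rec, "imperfect_triple")$matches
  expect_gt(nrow(m), 0L)
  for (i in seq_len(nrow(m))) {
    orients <- unit_orientations(m$first_unit_orientation[i], m$n_units[i])
    gaps <- as.integer(strsplit(m$insertions_per_gap[i], ",")[[1]])
    offs <- 5L * (seq_len(m$n_units[i]) - 1L) + c(0L, cumsum(gaps))
    recount <- sum(vapply(seq_len(m$n_units[i]), function(k) {
      match_unit(rec$sequence, m$start[i] + offs[k],
                 orients[k])$core_substitutions
    }, 0L))
    expect_equal(recount, m$substitutions_total[i])
  }
})

test_that("no two matches share a span key and duplicates collapse to the canonical alignment", {
  rec <- random_record(21)
  for (p in param_grid()) {
    m <- scan_record(rec, p)$matches
    key <- paste(m$start, m$end, m$first_unit_orientation)
    expect_false(any(duplicated(key)))
  }
  # a perfect minimal element inside an insertion-tolerant scan must be
  # explained with zero insertions/substitutions, not an inserted variant
  rec2 <- promoter_record("c", paste0(strrep("C", 20), "AGAACTTTCG",
                                      strrep("C", 20)))
  m2 <- scan_record(rec2, "imperfect_minimal")$matches
  perfect <- m2[m2$start == 20L & m2$end == 30L, ]
  expect_equal(perfect$substitutions_total, 0L)
  expect_equal(perfect$insertions_per_gap, "0")
})

test_that("matched-span sets grow monotonically with the budgets", {
  for (seed in 1:5) {
    rec <- random_record(200 + seed)
    spans <- function(s, i) {
      m <- scan_record(rec, scan_params(2L, s, min(i, 2L), i))$matches
      paste(m$start, m$end, m$first_unit_orientation)
    }
    expect_true(all(spans(0, 0) %in% spans(1, 0)))
    expect_true(all(spans(0, 0) %in% spans(0, 1)))
    expect_true(all(spans(1, 1) %in% spans(2, 2)))
  }
})

test_that("reverse-complement scanning mirrors spans and orientations", {
  rec <- random_record(31)
  rc <- promoter_record("rc", revcomp(rec$sequence))
  L <- rec$length
  for (preset in c("imperfect_minimal", "imperfect_triple")) {
    a <- scan_record(rec, preset)$matches
    b <- scan_record(rc, preset)$matches
    expect_equal(nrow(a), nrow(b))
    mirrored <- data.frame(start = L - b$end, end = L - b$start,
                           orient = ifelse(b$first_unit_orientation ==
                                             "GAA_type",
                                           "TTC_type", "GAA_type"))
    # mirroring also reverses which unit is first, so compare the span
    # multisets rather than per-match orientations
    expect_equal(sort(paste(a$start, a$end)),
                 sort(paste(mirrored$start, mirrored$end)))
  }
})

test_that("TSS distance and the 100-bp containment window are exact", {
  d <- tss_distance(40, 55, 100)
  expect_equal(d$distance_to_tss, 45L)
  expect_true(d$within_window)

  d <- tss_distance(0, 15, 100)  # exactly at the window edge
  expect_equal(d$distance_to_tss, 85L)
  expect_true(d$within_window)

  d <- tss_distance(45, 60, 50)  # crossing the TSS
  expect_equal(d$distance_to_tss, -10L)
  expect_false(d$within_window)

  # partial overlap with the window is not "within"
  expect_false(tss_distance(0, 15, 110)$within_window)
})

test_that("summaries pool presets without double counting perfect hits", {
  # one canonical element abutting the TSS, counted from its own preset
  # (the wide presets would also report its degenerate sub-alignments)
  rec <- promoter_record("p", paste0(strrep("C", 35), "AGAACATTCGAGAAT"))
  s <- summarize_hse(scan_record(rec, "canonical"), rec)
  expect_equal(s$count_canonical, 1L)
  expect_equal(s$count_imperfect_triple, 0L)
  expect_equal(s$count_within_100bp, 1L)
  expect_equal(s$union_total, 1L)

  # motif-free background: all-zero row
  bg <- promoter_record("z", strrep("C", 60))
  s0 <- summarize_hse(lapply(hse_classes, function(cl)
    scan_record(bg, cl)), bg)
  expect_equal(s0$union_total, 0L)
  expect_equal(s0$count_within_100bp, 0L)

  # mismatched records are a hard error
  other <- scan_record(promoter_record("q", strrep("C", 60)), "canonical")
  expect_error(summarize_hse(list(other), rec), "record")

  # union total is the plain sum of the four class counts
  rec2 <- random_record(55)
  s2 <- summarize_hse(lapply(hse_classes, function(cl)
    scan_record(rec2, cl)), rec2)
  expect_equal(s2$union_total,
               s2$count_canonical + s2$count_minimal_perfect +
                 s2$count_imperfect_triple + s2$count_imperfect_minimal)
  expect_lte(s2$count_within_100bp, s2$union_total)
  expect_lte(s2$dedup_span_total, s2$union_total)
})

test_that("the non-overlap post-filter keeps a left-to-right maximal subset", {
  rec <- random_record(61)
  m <- scan_promoters(rec, "imperfect_minimal")
  f <- filter_nonoverlapping(m)
  expect_lte(nrow(f), nrow(m))
  if (nrow(f) > 1L) {
    expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  }
})
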