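# Shared fixtures: seeded random records, parameter grids, comparisons.

random_record <- function(seed, length = 300L, gc = 0.5,
                          id = sprintf("seq%d", seed)) {
  promoter_record(id, sample_background(length, gc, seed))
}

# The full tolerance sweep: both unit counts, substitution budgets 0..2,
# and every admissible insertion-cap pair (per-gap cap <= total cap).
param_grid <- function() {
  grid <- list()
  for (nu in 2:3) for (ms in 0:2) for (tt in 0:2) for (pg in 0:tt) {
    grid[[length(grid) + 1L]] <- scan_params(nu, ms, pg, tt)
  }
  grid
}

strip_rows <- function(df) {
  rownames(df) <- NULL
  df
}

expect_same_matches <- function(a, b) {
  expect_identical(strip_rows(a), strip_rows(b))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

equal_class_mix <- c(canonical = 0.25, minimal_perfect = 0.25,
                     imperfect_triple = 0.25, imperfect_minimal = 0.25)

# A truth-table row is recovered when the scan of its record contains a
# match with exactly the planted span, orientation, substitution and
# insertion accounting.
truth_hit <- function(truth_row, matches) {
  sub_pos <- gsub("=[ACGTN]", "", truth_row$sub_plan)
  gaps <- integer(truth_row$n_units - 1L)
  if (truth_row$ins_plan != ".") {
    for (entry in strsplit(truth_row$ins_plan, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(entry, "=", fixed = TRUE)[[1]]
      gaps[as.integer(sub("^g", "", kv[1]))] <- nchar(kv[2])
    }
  }
  any(matches$start == truth_row$position &
        matches$end == truth_row$position + truth_row$width &
        matches$first_unit_orientation == truth_row$first_orientation &
        matches$substitutions_total == truth_row$substitutions_total &
        matches$substitution_positions == sub_pos &
        matches$insertions_per_gap == paste(gaps, collapse = ",") &
        matches$class == truth_row$expected_class)
}
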