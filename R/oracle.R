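# Brute-force oracle: explicit template expansion and regex matching.
#
# Independent reference implementation of the HSE search, used to audit
# the scanner. Every combination of first-unit orientation, core
# substitution placement (within budget) and gap-insertion vector is
# expanded into one fixed-length degenerate template; templates are slid
# over the sequence with the regex engine (overlapping hits via a
# zero-width lookahead). A substituted core position is a negated
# character class (any base other than the consensus, N included), a
# literal core position matches only its consensus base (so N fails), and
# wildcard positions match any of A/C/G/T/N. This path shares no matching
# code with the scanner, which counts mismatches arithmetically.

# Recursive gap-vector enumeration (deliberately distinct from the
# scanner's expand.grid-based enumeration), lexicographic order.
oracle_gap_vectors <- function(n_gaps, per_gap, total) {
  if (n_gaps == 0L) return(list(integer(0)))
  out <- list()
  for (v in 0:per_gap) {
    if (v > total) break
    for (rest in oracle_gap_vectors(n_gaps - 1L, per_gap, total - v)) {
      out[[length(out) + 1L]] <- c(v, rest)
    }
  }
  out
}

# Substitution placements: subsets of the 3*n core positions with size
# <= budget and per-unit load <= cap, as two-column (unit, pos) matrices.
oracle_placements <- function(n_units, max_total, per_unit_cap) {
  npos <- 3L * n_units
  unit_of <- rep(seq_len(n_units), each = 3L)
  pos_of <- rep(1:3, times = n_units)
  out <- list(cbind(unit = integer(0), pos = integer(0)))
  for (size in seq_len(min(max_total, npos))) {
    sets <- utils::combn(npos, size)
    for (j in seq_len(ncol(sets))) {
      ids <- sets[, j]
      if (max(tabulate(unit_of[ids], n_units)) > per_unit_cap) next
      out[[length(out) + 1L]] <- cbind(unit = unit_of[ids],
                                       pos = pos_of[ids])
    }
  }
  out
}

#' Enumerate the concrete search templates for an envelope
#'
#' Exhaustively lists every (first orientation) x (substitution placement
#' within budget) x (gap-insertion vector within caps) combination as a
#' fixed-length degenerate template. The canonical preset yields exactly
#' the two canonical 15-bp forms and the minimal preset the two perfect
#' 10-bp forms.
#'
#' @param params [scan_params()] envelope or preset name.
#' @param max_templates Guard against combinatorial blow-up; exceeding it
#'   is an error.
#' @return An `hse_template_set`: list with `params` and `templates`,
#'   each template holding `first_orientation`, `placement` (unit/pos
#'   matrix), `ins` (gap vector), `width` and `regex`.
#' @examples
#' length(enumerate_templates("canonical")$templates)  # 2
#' @export
enumerate_templates <- function(params, max_templates = 1e6) {
  if (is.character(params)) params <- hse_preset(params)
  stopifnot(inherits(params, "hse_scan_params"))
  n <- params$n_units
  placements <- oracle_placements(n, params$max_subs_total,
                                  params$max_subs_per_unit)
  gaps <- oracle_gap_vectors(n - 1L, params$max_ins_per_gap,
                             params$max_ins_total)
  count <- 2 * length(placements) * length(gaps)
  if (count > max_templates) {
    stop("envelope expands to ", count, " templates (cap ", max_templates,
         ")", call. = FALSE)
  }
  wild <- "[ACGTN]"
  templates <- list()
  for (first in c("GAA_type", "TTC_type")) {
    orients <- unit_orientations(first, n)
    for (pl in placements) {
      for (iv in gaps) {
        toks <- character(0)
        for (k in seq_len(n)) {
          cons <- core_bases(orients[k])
          core <- character(3)
          for (j in 1:3) {
            subbed <- any(pl[, "unit"] == k & pl[, "pos"] == j)
            core[j] <- if (subbed) paste0("[^", cons[j], "]") else cons[j]
          }
          toks <- c(toks, wild, core, wild)
          if (k < n) toks <- c(toks, rep(wild, iv[k]))
        }
        templates[[length(templates) + 1L]] <- list(
          first_orientation = first,
          placement = pl,
          ins = as.integer(iv),
          width = 5L * n + sum(iv),
          regex = paste(toks, collapse = "")
        )
      }
    }
  }
  structure(list(params = params, templates = templates),
            class = "hse_template_set")
}

#' @export
print.hse_template_set <- function(x, ...) {
  cat(sprintf("HSE template set: %d template(s) for a %d-unit envelope\n",
              length(x$templates), x$params$n_units))
  invisible(x)
}

#' Brute-force oracle scan
#'
#' Slides every template from [enumerate_templates()] over the sequence
#' and converts hits to matches, applying the same canonicalization rule
#' as the scanner (minimal substitutions, then lexicographically smallest
#' gap vector, per (start, end, orientation) span). Transparent and slow
#' by design; intended for equivalence testing of [scan_record()].
#'
#' @param record Promoter record.
#' @param params [scan_params()] envelope or preset name.
#' @param max_templates Passed to [enumerate_templates()].
#' @return An `hse_match_set` identical in structure to [scan_record()]'s.
#' @export
oracle_scan <- function(record, params, max_templates = 1e6) {
  if (is.character(params)) params <- hse_preset(params)
  rec <- as_promoter_record(record)
  tset <- enumerate_templates(params, max_templates)
  seq_str <- rec$sequence
  rows <- list()
  for (tpl in tset$templates) {
    hits <- gregexpr(paste0("(?=", tpl$regex, ")"), seq_str,
                     perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (h in as.integer(hits)) {
      rows[[length(rows) + 1L]] <- list(
        start = h - 1L, end = h - 1L + tpl$width,
        first = tpl$first_orientation,
        subs = nrow(tpl$placement),
        su = as.integer(tpl$placement[, "unit"]),
        sp = as.integer(tpl$placement[, "pos"]),
        iv = tpl$ins)
    }
  }
  if (length(rows) == 0L) {
    return(new_match_set(rec$record_id, params, empty_hse_matches()))
  }
  start <- vapply(rows, `[[`, 0L, "start")
  end <- vapply(rows, `[[`, 0L, "end")
  first <- vapply(rows, `[[`, "", "first")
  subs <- vapply(rows, `[[`, 0L, "subs")
  gap <- vapply(rows, function(x) format_gap_vector(x$iv), "")
  # Canonical alignment per span key, selected group-wise.
  key <- paste(start, end, first, sep = "|")
  pick <- vapply(split(seq_along(rows), key), function(ix) {
    ix[order(subs[ix], gap[ix])][1]
  }, 0L)
  pick <- sort(unname(pick))
  matches <- hse_match_frame(
    record_id = rec$record_id,
    sequence = seq_str,
    start = start[pick],
    end = end[pick],
    n_units = params$n_units,
    first_unit_orientation = first[pick],
    substitutions_total = subs[pick],
    substitution_positions = vapply(rows[pick], function(x)
      format_sub_positions(x$su, x$sp), ""),
    subs_at_core_pos1 = vapply(rows[pick], function(x)
      sum(x$sp == 1L), 0L),
    insertions_per_gap = gap[pick],
    insertions_total = vapply(rows[pick], function(x)
      as.integer(sum(x$iv)), 0L)
  )
  new_match_set(rec$record_id, params, sort_matches(matches))
}
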