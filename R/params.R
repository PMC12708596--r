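#' HSE class labels
#'
#' The four element classes recognised by the scanner, in canonical order:
#' `canonical` (three alternating nGAAn units, no substitutions, no
#' insertions, 15 bp), `minimal_perfect` (two alternating units, perfect,
#' 10 bp), `imperfect_triple` (three units carrying at least one core
#' substitution and/or inter-unit insertion) and `imperfect_minimal` (the
#' two-unit analogue).
#'
#' @format Character vector of length 4.
#' @export
hse_classes <- c("canonical", "minimal_perfect",
                 "imperfect_triple", "imperfect_minimal")

core_bases <- function(orientation) {
  switch(orientation,
         GAA_type = c("G", "A", "A"),
         TTC_type = c("T", "T", "C"),
         stop("unknown orientation: ", orientation))
}

unit_orientations <- function(first_orientation, n_units) {
  other <- if (first_orientation == "GAA_type") "TTC_type" else "GAA_type"
  rep_len(c(first_orientation, other), n_units)
}

#' Scan parameter envelope
#'
#' Defines the tolerance envelope for one HSE search: how many pentamer
#' units to require, the total substitution budget over all unit cores,
#' and the insertion budget between adjacent units. Units tile as adjacent
#' 5-base blocks; each inter-unit gap may carry up to `max_ins_per_gap`
#' extra bases, with at most `max_ins_total` extra bases over all gaps.
#'
#' @param n_units Number of alternating nGAAn pentamer units, 2 or 3.
#' @param max_subs_total Cap on summed core substitutions across all units.
#' @param max_ins_per_gap Cap on extra bases in each inter-unit gap.
#' @param max_ins_total Cap on summed insertions; must be >=
#'   `max_ins_per_gap`.
#' @param max_subs_per_unit Optional per-unit substitution cap (default 3,
#'   i.e. unconstrained beyond the core length).
#' @return An object of class `hse_scan_params`.
#' @seealso [hse_preset()] for the named presets used by the classifier.
#' @examples
#' scan_params(3, 2, 2, 2)          # imperfect triple envelope
#' hse_preset("minimal_perfect")    # equivalent to scan_params(2, 0, 0, 0)
#' @export
scan_params <- function(n_units, max_subs_total, max_ins_per_gap,
                        max_ins_total, max_subs_per_unit = 3L) {
  n_units <- as.integer(n_units)
  if (length(n_units) != 1L || is.na(n_units) || !n_units %in% c(2L, 3L)) {
    stop("n_units must be 2 or 3", call. = FALSE)
  }
  max_subs_total <- as.integer(max_subs_total)
  max_ins_per_gap <- as.integer(max_ins_per_gap)
  max_ins_total <- as.integer(max_ins_total)
  max_subs_per_unit <- as.integer(max_subs_per_unit)
  for (v in list(max_subs_total, max_ins_per_gap, max_ins_total,
                 max_subs_per_unit)) {
    if (length(v) != 1L || is.na(v) || v < 0L) {
      stop("scan parameter caps must be single non-negative integers",
           call. = FALSE)
    }
  }
  if (max_ins_per_gap > max_ins_total) {
    stop("max_ins_per_gap must not exceed max_ins_total", call. = FALSE)
  }
  structure(
    list(n_units = n_units,
         max_subs_total = max_subs_total,
         max_ins_per_gap = max_ins_per_gap,
         max_ins_total = max_ins_total,
         max_subs_per_unit = max_subs_per_unit),
    class = "hse_scan_params"
  )
}

#' @export
print.hse_scan_params <- function(x, ...) {
  cat(sprintf(
    "HSE scan params: %d units, <=%d core substitutions, insertions <=%d/gap, <=%d total\n",
    x$n_units, x$max_subs_total, x$max_ins_per_gap, x$max_ins_total))
  invisible(x)
}

#' Named scan presets
#'
#' The four preset envelopes corresponding to the HSE classes:
#' `canonical` = (3 units, 0 substitutions, 0 insertions),
#' `minimal_perfect` = (2, 0, 0, 0),
#' `imperfect_triple` = (3, 2, 2, 2) and
#' `imperfect_minimal` = (2, 1, 2, 2). The imperfect presets follow the
#' budgets under which the element tallies are reported: up to two core
#' substitutions for triple repeats, up to one for minimal repeats, with
#' one to two inserted bases allowed per gap and in total.
#'
#' @param name One of the strings in [hse_classes].
#' @return An `hse_scan_params` object.
#' @export
hse_preset <- function(name) {
  switch(name,
         canonical         = scan_params(3L, 0L, 0L, 0L),
         minimal_perfect   = scan_params(2L, 0L, 0L, 0L),
         imperfect_triple  = scan_params(3L, 2L, 2L, 2L),
         imperfect_minimal = scan_params(2L, 1L, 2L, 2L),
         stop("unknown preset: ", name, call. = FALSE))
}

#' Classify an HSE match
#'
#' Maps the unit count and degeneracy load of a match to its class label:
#' a perfect three-unit element is `canonical`, a perfect two-unit element
#' is `minimal_perfect`, and any element carrying at least one core
#' substitution or inter-unit insertion is `imperfect_triple` or
#' `imperfect_minimal` according to its unit count. The four labels
#' partition the whole parameter envelope.
#'
#' @param n_units Integer vector, each element 2 or 3.
#' @param substitutions_total Integer vector of summed core substitutions.
#' @param insertions_total Integer vector of summed inter-unit insertions.
#' @return Character vector of class labels (see [hse_classes]).
#' @examples
#' classify_hse(3, 0, 0)  # "canonical"
#' classify_hse(2, 0, 0)  # "minimal_perfect"
#' classify_hse(3, 1, 2)  # "imperfect_triple"
#' @export
classify_hse <- function(n_units, substitutions_total, insertions_total) {
  len <- max(length(n_units), length(substitutions_total),
             length(insertions_total))
  n_units <- rep_len(as.integer(n_units), len)
  substitutions_total <- rep_len(as.integer(substitutions_total), len)
  insertions_total <- rep_len(as.integer(insertions_total), len)
  if (any(is.na(n_units)) || !all(n_units %in% c(2L, 3L))) {
    stop("n_units must be 2 or 3", call. = FALSE)
  }
  if (any(substitutions_total < 0L) || any(insertions_total < 0L)) {
    stop("substitution and insertion counts must be non-negative",
         call. = FALSE)
  }
  degenerate <- substitutions_total + insertions_total > 0L
  ifelse(n_units == 3L,
         ifelse(degenerate, "imperfect_triple", "canonical"),
         ifelse(degenerate, "imperfect_minimal", "minimal_perfect"))
}
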