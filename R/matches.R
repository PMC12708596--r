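# Match container: typed assembly, ordering, and report writers.
#
# Internal coordinates are 0-based half-open [start, end) on the sense
# strand; the TSV report is 1-based inclusive and BED is 0-based half-open.

match_columns <- c("record_id", "start", "end", "n_units",
                   "first_unit_orientation", "substitutions_total",
                   "substitution_positions", "subs_at_core_pos1",
                   "insertions_per_gap", "insertions_total", "class",
                   "distance_to_tss", "within_100bp_of_tss", "rank",
                   "matched_sequence")

empty_hse_matches <- function() {
  data.frame(record_id = character(), start = integer(), end = integer(),
             n_units = integer(), first_unit_orientation = character(),
             substitutions_total = integer(),
             substitution_positions = character(),
             subs_at_core_pos1 = integer(),
             insertions_per_gap = character(),
             insertions_total = integer(), class = character(),
             distance_to_tss = integer(),
             within_100bp_of_tss = logical(), rank = integer(),
             matched_sequence = character(), stringsAsFactors = FALSE)
}

# Assemble a typed match frame from parallel vectors; class labels and
# matched subsequences are derived here so both search paths report them
# identically.
hse_match_frame <- function(record_id, sequence, start, end, n_units,
                            first_unit_orientation, substitutions_total,
                            substitution_positions, subs_at_core_pos1,
                            insertions_per_gap, insertions_total) {
  if (length(start) == 0L) return(empty_hse_matches())
  data.frame(
    record_id = as.character(record_id),
    start = as.integer(start),
    end = as.integer(end),
    n_units = as.integer(n_units),
    first_unit_orientation = as.character(first_unit_orientation),
    substitutions_total = as.integer(substitutions_total),
    substitution_positions = as.character(substitution_positions),
    subs_at_core_pos1 = as.integer(subs_at_core_pos1),
    insertions_per_gap = as.character(insertions_per_gap),
    insertions_total = as.integer(insertions_total),
    class = classify_hse(n_units, substitutions_total, insertions_total),
    distance_to_tss = NA_integer_,
    within_100bp_of_tss = NA,
    rank = NA_integer_,
    matched_sequence = substring(sequence, as.integer(start) + 1L,
                                 as.integer(end)),
    stringsAsFactors = FALSE
  )
}

# "u<unit>p<corepos>" entries joined by ","; "." when perfect.
format_sub_positions <- function(units, positions) {
  if (length(units) == 0L) return(".")
  paste(sprintf("u%dp%d", units, positions), collapse = ",")
}

format_gap_vector <- function(ins) paste(ins, collapse = ",")

parse_gap_vector <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])

count_pos1_subs <- function(sub_positions) {
  vapply(sub_positions, function(s) {
    if (identical(s, ".")) return(0L)
    sum(grepl("p1$", strsplit(s, ",", fixed = TRUE)[[1]]))
  }, 0L, USE.NAMES = FALSE)
}

sort_matches <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  ord <- order(matches$start, matches$end, matches$first_unit_orientation)
  out <- matches[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Report/record ordering: records in first-appearance order, then span.
report_order <- function(matches) {
  rid <- match(matches$record_id, unique(matches$record_id))
  order(rid, matches$start, matches$end, matches$first_unit_orientation)
}

new_match_set <- function(record_id, params, matches) {
  structure(list(record_id = record_id, params = params,
                 matches = matches),
            class = "hse_match_set")
}

#' @export
print.hse_match_set <- function(x, ...) {
  cat(sprintf("HSE match set for '%s': %d match(es)\n",
              x$record_id, nrow(x$matches)))
  invisible(x)
}

tsv_columns <- c("record_id", "start_1based", "end_1based_inclusive",
                 "n_units", "first_unit_orientation", "substitutions_total",
                 "substitution_positions", "insertions_per_gap",
                 "insertions_total", "class", "distance_to_tss",
                 "within_100bp_of_tss", "rank", "matched_sequence")

check_out_path <- function(out_path) {
  dir <- dirname(out_path)
  if (!dir.exists(dir)) {
    stop("cannot write '", out_path, "': directory does not exist",
         call. = FALSE)
  }
}

#' Write a match report as a delimited table
#'
#' Writes one row per match, sorted by record (in first-appearance order)
#' and span. Coordinates are reported 1-based inclusive
#' (`start_1based`/`end_1based_inclusive`); the same interval appears
#' 0-based half-open in the BED writer.
#'
#' @param matches Match frame as produced by [scan_record()] /
#'   [scan_promoters()] (annotation and ranks may be `NA`).
#' @param out_path Output file path.
#' @return Invisibly, `out_path`.
#' @seealso [read_matches_tsv()] for the exact inverse,
#'   [write_matches_bed()].
#' @export
write_matches_tsv <- function(matches, out_path) {
  check_out_path(out_path)
  m <- matches[report_order(matches), , drop = FALSE]
  out <- data.frame(
    record_id = m$record_id,
    start_1based = m$start + 1L,
    end_1based_inclusive = m$end,
    n_units = m$n_units,
    first_unit_orientation = m$first_unit_orientation,
    substitutions_total = m$substitutions_total,
    substitution_positions = m$substitution_positions,
    insertions_per_gap = m$insertions_per_gap,
    insertions_total = m$insertions_total,
    class = m$class,
    distance_to_tss = m$distance_to_tss,
    within_100bp_of_tss = m$within_100bp_of_tss,
    rank = m$rank,
    matched_sequence = m$matched_sequence,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(out_path)
}

#' Read a match report written by [write_matches_tsv()]
#'
#' Reconstructs the internal match frame (0-based half-open coordinates)
#' bit-exactly from the 1-based report.
#'
#' @param path Path to the TSV report.
#' @return Match frame in internal representation.
#' @export
read_matches_tsv <- function(path) {
  if (!file.exists(path)) stop("match report not found: ", path,
                               call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = c("character", "integer", "integer",
                                          "integer", "character", "integer",
                                          "character", "character",
                                          "integer", "character", "integer",
                                          "logical", "integer", "character"))
  if (!identical(names(raw), tsv_columns)) {
    stop("unexpected columns in match report: ", path, call. = FALSE)
  }
  if (nrow(raw) == 0L) return(empty_hse_matches())
  out <- data.frame(
    record_id = raw$record_id,
    start = raw$start_1based - 1L,
    end = raw$end_1based_inclusive,
    n_units = raw$n_units,
    first_unit_orientation = raw$first_unit_orientation,
    substitutions_total = raw$substitutions_total,
    substitution_positions = raw$substitution_positions,
    subs_at_core_pos1 = count_pos1_subs(raw$substitution_positions),
    insertions_per_gap = raw$insertions_per_gap,
    insertions_total = raw$insertions_total,
    class = raw$class,
    distance_to_tss = raw$distance_to_tss,
    within_100bp_of_tss = raw$within_100bp_of_tss,
    rank = raw$rank,
    matched_sequence = raw$matched_sequence,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write matches as BED6
#'
#' One BED6 line per match: `chrom` is the record ID, coordinates are
#' 0-based half-open, `name` is the class label, `score` is the rank
#' scaled linearly to \[0, 1000\] within each record (best rank -> 1000),
#' and `strand` is always `+` (scanning is sense-strand only; the motif
#' family is closed under reverse complement).
#'
#' @param matches Match frame with ranks assigned (see [rank_matches()]).
#' @param out_path Output file path.
#' @return Invisibly, `out_path`.
#' @export
write_matches_bed <- function(matches, out_path) {
  check_out_path(out_path)
  if (nrow(matches) == 0L) {
    writeLines(character(), out_path)
    return(invisible(out_path))
  }
  if (any(is.na(matches$rank))) {
    stop("BED output requires ranks; run rank_matches() first",
         call. = FALSE)
  }
  m <- matches[report_order(matches), , drop = FALSE]
  nmax <- stats::ave(m$rank, m$record_id, FUN = max)
  score <- as.integer(round(1000 * (nmax - m$rank + 1) / nmax))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t+", m$record_id, m$start, m$end,
                     m$class, score), out_path)
  invisible(out_path)
}
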