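# Per-promoter class summaries.

dedupe_matches <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  m <- sort_matches(matches)
  m[!duplicated(m[c("start", "end", "first_unit_orientation")]), ,
    drop = FALSE]
}

summary_row <- function(record_id, matches, tss) {
  d <- if (nrow(matches)) {
    tss_distance(matches$start, matches$end, tss)$within_window
  } else logical(0)
  counts <- vapply(hse_classes, function(cl) sum(matches$class == cl), 0L)
  data.frame(
    record_id = record_id,
    count_canonical = counts[["canonical"]],
    count_minimal_perfect = counts[["minimal_perfect"]],
    count_imperfect_triple = counts[["imperfect_triple"]],
    count_imperfect_minimal = counts[["imperfect_minimal"]],
    count_within_100bp = sum(d),
    union_total = as.integer(sum(counts)),
    dedup_span_total = nrow(unique(matches[c("start", "end")])),
    stringsAsFactors = FALSE
  )
}

#' Summarize per-preset match sets for one promoter
#'
#' Pools the match sets obtained for one record under several envelopes,
#' collapses alignments found under more than one envelope (a perfect
#' element found under a wider imperfect envelope is counted once, as
#' perfect, never as imperfect), and tallies matches by class. The union
#' total is the plain sum of the four class counts; a deduplicated span
#' count (distinct (start, end) intervals) is reported alongside for
#' users who want cross-class overlap collapsed.
#'
#' @param matchsets List of `hse_match_set` objects (or a single one),
#'   all produced from `record`.
#' @param record The promoter record the sets were scanned from.
#' @return One-row data frame: per-class counts, `count_within_100bp`
#'   (over all classes), `union_total` and `dedup_span_total`.
#' @export
summarize_hse <- function(matchsets, record) {
  if (inherits(matchsets, "hse_match_set")) matchsets <- list(matchsets)
  rec <- as_promoter_record(record)
  ids <- vapply(matchsets, `[[`, "", "record_id")
  if (any(ids != rec$record_id)) {
    stop("match sets come from record(s) ",
         paste(unique(ids[ids != rec$record_id]), collapse = ", "),
         " but the record is '", rec$record_id, "'", call. = FALSE)
  }
  pooled <- dedupe_matches(do.call(rbind, lapply(matchsets, `[[`,
                                                 "matches")))
  summary_row(rec$record_id, pooled, rec$tss)
}

#' Summarize a promoter set end to end
#'
#' Convenience wrapper: scans every record under the given presets and
#' returns one summary row per record (see [summarize_hse()]).
#'
#' @param promoters Promoter record frame.
#' @param presets Preset names or [scan_params()] list.
#' @return Data frame with one row per record, in input order.
#' @export
summarize_promoters <- function(promoters, presets = hse_classes) {
  matches <- scan_promoters(promoters, presets)
  out <- do.call(rbind, lapply(seq_len(nrow(promoters)), function(i) {
    m <- matches[matches$record_id == promoters$record_id[i], ,
                 drop = FALSE]
    summary_row(promoters$record_id[i], m, promoters$tss[i])
  }))
  rownames(out) <- NULL
  out
}
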