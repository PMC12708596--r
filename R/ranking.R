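# Ordinal ranking of detected elements by predicted functionality.

rank_key_components <- c("substitutions_total", "subs_at_core_pos1",
                         "insertions_total", "tss_distance_abs")

#' Rank HSE matches by predicted functionality
#'
#' Orders matches by how close they are to a fully functional element:
#' fewer core substitutions first, then fewer substitutions at core
#' position 1 (the G of GAA / first T of TTC, taken as the most
#' disruptive substitution type), then fewer inter-unit insertions, then
#' smaller absolute distance to the TSS. Ties are broken
#' deterministically by start position (then end, then orientation), so
#' ranks are always the permutation 1..n.
#'
#' The key composition is configurable: `key` may reorder or drop the
#' named components; the positional tie-break is always appended.
#'
#' @param matches Match frame with `distance_to_tss` resolved (see
#'   [annotate_tss()]).
#' @param key Character vector, a subset/permutation of
#'   `c("substitutions_total", "subs_at_core_pos1", "insertions_total",
#'   "tss_distance_abs")`.
#' @return A copy of `matches` with `rank` assigned (input is not
#'   mutated).
#' @export
rank_matches <- function(matches, key = rank_key_components) {
  if (!all(key %in% rank_key_components)) {
    stop("unknown rank key component(s): ",
         paste(setdiff(key, rank_key_components), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(matches) == 0L) return(matches)
  if (any(is.na(matches$distance_to_tss))) {
    stop("distance_to_tss must be resolved before ranking; ",
         "run annotate_tss()", call. = FALSE)
  }
  cols <- list(
    substitutions_total = matches$substitutions_total,
    subs_at_core_pos1 = matches$subs_at_core_pos1,
    insertions_total = matches$insertions_total,
    tss_distance_abs = abs(matches$distance_to_tss)
  )
  ord <- do.call(order, c(cols[key],
                          list(matches$start, matches$end,
                               matches$first_unit_orientation)))
  out <- matches
  out$rank[ord] <- seq_len(nrow(matches))
  out
}

# Per-record ranking for multi-record match frames.
rank_by_record <- function(matches, key = rank_key_components) {
  if (nrow(matches) == 0L) return(matches)
  parts <- lapply(unique(matches$record_id), function(id) {
    rank_matches(matches[matches$record_id == id, , drop = FALSE], key)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
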