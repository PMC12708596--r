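# HSE scanner: enumerate every admissible alignment of alternating nGAAn
# pentamer units over a promoter sequence.
#
# A match is a tiling of 2 or 3 five-base units (wildcard + 3-base core +
# wildcard) with strictly alternating core orientation (GAA on the sense
# strand vs its reverse complement TTC), separated by gaps of 0 extra
# bases plus up to the configured insertion allowance. Core mismatches are
# counted per unit (N in a core counts as a substitution; wildcard
# positions never do). Alignments sharing (start, end, orientation) but
# differing in gap placement are collapsed to the canonical alignment:
# minimal substitutions, then lexicographically smallest gap vector.

#' Match a single pentamer unit
#'
#' Tests one 5-base window as an nGAAn unit in the given orientation and
#' reports the Hamming distance of its 3-base core to GAA (`GAA_type`) or
#' TTC (`TTC_type`). The first and fifth bases are unconstrained
#' wildcards; an N in a core position counts as a substitution.
#'
#' @param sequence DNA string.
#' @param pos 0-based offset of the unit's first base; `pos + 5` must not
#'   exceed the sequence length.
#' @param orientation `"GAA_type"` or `"TTC_type"`.
#' @return List with `start`, `orientation`, `core_substitutions` and
#'   `substituted_core_positions` (positions within the core, 1 = the G of
#'   GAA / first T of TTC).
#' @examples
#' match_unit("AGAAT", 0, "GAA_type")$core_substitutions  # 0
#' match_unit("ACAAT", 0, "GAA_type")$substituted_core_positions  # 1
#' @export
match_unit <- function(sequence, pos, orientation) {
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L || pos + 5L > nchar(sequence)) {
    stop("unit window [", pos, ", ", pos + 5L,
         ") out of range for sequence of length ", nchar(sequence),
         call. = FALSE)
  }
  core <- strsplit(substring(sequence, pos + 2L, pos + 4L), "")[[1]]
  cons <- core_bases(orientation)
  subst <- which(core != cons)
  list(start = pos, orientation = orientation,
       core_substitutions = length(subst),
       substituted_core_positions = as.integer(subst))
}

# All gap-insertion vectors (one entry per inter-unit gap, each
# 0..per_gap, summing to <= total), in lexicographic order.
scan_ins_vectors <- function(n_gaps, per_gap, total) {
  g <- as.matrix(expand.grid(rep(list(0:per_gap), n_gaps),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g <- g[rowSums(g) <= total, , drop = FALSE]
  ord <- do.call(order, lapply(seq_len(ncol(g)), function(j) g[, j]))
  g[ord, , drop = FALSE]
}

#' Scan one promoter record for HSE matches
#'
#' Enumerates every distinct admissible alignment (start position,
#' alternating orientation assignment starting with either `GAA_type` or
#' `TTC_type`, and gap-insertion vector) whose summed core substitutions
#' and insertions fall within the envelope, then collapses alignments
#' identical in (start, end, orientation sequence) to the canonical one
#' (minimal substitutions, then lexicographically smallest gap vector).
#'
#' Scanning is sense-strand only: the motif family is closed under
#' reverse complement (the reverse complement of nGAAnnTTCnnGAAn is
#' nTTCnnGAAnnTTCn), so one-strand scanning already finds every element
#' and avoids double counting. Overlapping matches at different spans are
#' all reported; see [filter_nonoverlapping()] for an optional post-filter.
#'
#' @param record Promoter record (one-row data frame or list with
#'   `record_id`, `sequence`, `tss`).
#' @param params An [scan_params()] envelope or preset name from
#'   [hse_classes].
#' @return An `hse_match_set`: list with `record_id`, `params` and
#'   `matches` (a match frame sorted by start, end, orientation).
#' @examples
#' rec <- promoter_record("p1", "AGAACATTCGAGAAT")
#' scan_record(rec, "canonical")$matches
#' @export
scan_record <- function(record, params) {
  if (is.character(params)) params <- hse_preset(params)
  stopifnot(inherits(params, "hse_scan_params"))
  rec <- as_promoter_record(record)
  s <- strsplit(rec$sequence, "")[[1]]
  L <- length(s)
  n <- params$n_units
  empty <- new_match_set(rec$record_id, params, empty_hse_matches())
  if (L < 5L * n) return(empty)

  # Per unit-start core mismatch flags for both orientations.
  maxu <- L - 4L
  u <- seq_len(maxu)
  flags <- list(
    GAA_type = cbind(s[u + 1L] != "G", s[u + 2L] != "A", s[u + 3L] != "A"),
    TTC_type = cbind(s[u + 1L] != "T", s[u + 2L] != "T", s[u + 3L] != "C")
  )
  counts <- lapply(flags, rowSums)

  ivs <- scan_ins_vectors(n - 1L, params$max_ins_per_gap,
                          params$max_ins_total)
  cand <- list()
  for (first in c("GAA_type", "TTC_type")) {
    orients <- unit_orientations(first, n)
    for (r in seq_len(nrow(ivs))) {
      iv <- ivs[r, ]
      width <- 5L * n + sum(iv)
      if (width > L) next
      offs <- 5L * (seq_len(n) - 1L) + c(0L, cumsum(iv))
      starts <- seq_len(L - width + 1L)  # 1-based first-unit starts
      pu <- matrix(0L, nrow = length(starts), ncol = n)
      for (k in seq_len(n)) {
        pu[, k] <- counts[[orients[k]]][starts + offs[k]]
      }
      tot <- as.integer(rowSums(pu))
      ok <- tot <= params$max_subs_total &
        rowSums(pu > params$max_subs_per_unit) == 0L
      for (i in which(ok)) {
        st <- starts[i]
        su <- integer(0); sp <- integer(0)
        for (k in seq_len(n)) {
          hit <- which(flags[[orients[k]]][st + offs[k], ])
          su <- c(su, rep.int(k, length(hit)))
          sp <- c(sp, hit)
        }
        cand[[length(cand) + 1L]] <- list(
          start = st - 1L, end = st - 1L + width, first = first,
          subs = tot[i], su = su, sp = sp, iv = iv)
      }
    }
  }
  if (length(cand) == 0L) return(empty)

  df <- data.frame(
    start = vapply(cand, `[[`, 0L, "start"),
    end = vapply(cand, `[[`, 0L, "end"),
    first = vapply(cand, `[[`, "", "first"),
    subs = vapply(cand, `[[`, 0L, "subs"),
    gap = vapply(cand, function(x) format_gap_vector(x$iv), ""),
    idx = seq_along(cand),
    stringsAsFactors = FALSE
  )
  # Canonicalization: one alignment per (start, end, orientation) key.
  ord <- order(df$start, df$end, df$first, df$subs, df$gap)
  df <- df[ord, , drop = FALSE]
  keep <- !duplicated(df[c("start", "end", "first")])
  df <- df[keep, , drop = FALSE]

  picked <- cand[df$idx]
  matches <- hse_match_frame(
    record_id = rec$record_id,
    sequence = rec$sequence,
    start = df$start,
    end = df$end,
    n_units = n,
    first_unit_orientation = df$first,
    substitutions_total = df$subs,
    substitution_positions = vapply(picked, function(x)
      format_sub_positions(x$su, x$sp), ""),
    subs_at_core_pos1 = vapply(picked, function(x)
      sum(x$sp == 1L), 0L),
    insertions_per_gap = df$gap,
    insertions_total = vapply(picked, function(x)
      as.integer(sum(x$iv)), 0L)
  )
  new_match_set(rec$record_id, params, sort_matches(matches))
}

#' TSS distance and proximity window
#'
#' The distance from a match to the TSS is `tss - end`: the number of
#' bases between the last matched base and the first transcribed base
#' (0 when the match abuts the TSS, negative when it crosses or lies past
#' it). A match is "within 100 bp of the TSS" only when it is entirely
#' contained in the 100-bp window upstream of the TSS, i.e.
#' `start >= tss - 100` and `end <= tss`.
#'
#' @param start,end 0-based half-open match span (vectors).
#' @param tss 0-based TSS offset (recycled).
#' @param window Window width in bp upstream of the TSS (default 100).
#' @return Data frame with `distance_to_tss` and `within_window`.
#' @export
tss_distance <- function(start, end, tss, window = 100L) {
  start <- as.integer(start); end <- as.integer(end)
  tss <- as.integer(tss)
  data.frame(distance_to_tss = tss - end,
             within_window = start >= tss - as.integer(window) &
               end <= tss)
}

#' Annotate matches with TSS distance
#'
#' Fills the `distance_to_tss` and `within_100bp_of_tss` columns of a
#' match frame from the per-record TSS offsets.
#'
#' @param matches Match frame.
#' @param promoters Promoter record frame (from [read_promoters()]).
#' @return The annotated match frame.
#' @export
annotate_tss <- function(matches, promoters) {
  if (nrow(matches) == 0L) return(matches)
  j <- match(matches$record_id, promoters$record_id)
  if (anyNA(j)) {
    stop("matches reference record '",
         matches$record_id[which(is.na(j))[1]],
         "' absent from the promoter set", call. = FALSE)
  }
  d <- tss_distance(matches$start, matches$end, promoters$tss[j])
  matches$distance_to_tss <- d$distance_to_tss
  matches$within_100bp_of_tss <- d$within_window
  matches
}

#' Scan a promoter set under one or more presets
#'
#' Runs [scan_record()] for every record under every requested envelope,
#' pools the results, removes duplicate alignments found under more than
#' one envelope (perfect elements are also found under the wider imperfect
#' envelopes), and annotates TSS distances.
#'
#' @param promoters Promoter record frame.
#' @param presets Character vector of preset names (default all four) or a
#'   list of [scan_params()] objects.
#' @return Combined annotated match frame.
#' @export
scan_promoters <- function(promoters, presets = hse_classes) {
  if (is.character(presets)) presets <- lapply(presets, hse_preset)
  if (inherits(presets, "hse_scan_params")) presets <- list(presets)
  out <- lapply(seq_len(nrow(promoters)), function(i) {
    rec <- promoters[i, , drop = FALSE]
    per <- lapply(presets, function(p) scan_record(rec, p)$matches)
    m <- do.call(rbind, per)
    if (nrow(m) == 0L) return(m)
    m <- sort_matches(m)
    m[!duplicated(m[c("start", "end", "first_unit_orientation")]), ,
      drop = FALSE]
  })
  combined <- do.call(rbind, out)
  rownames(combined) <- NULL
  annotate_tss(combined, promoters)
}

#' Keep a maximal non-overlapping subset of matches
#'
#' Optional post-filter: within each record, walks matches left to right
#' (by start, then end) and keeps each match that does not overlap the
#' previously kept one.
#'
#' @param matches Match frame.
#' @return Filtered match frame.
#' @export
filter_nonoverlapping <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  keep <- logical(nrow(matches))
  for (id in unique(matches$record_id)) {
    idx <- which(matches$record_id == id)
    idx <- idx[order(matches$start[idx], matches$end[idx])]
    last_end <- -1L
    for (i in idx) {
      if (matches$start[i] >= last_end) {
        keep[i] <- TRUE
        last_end <- matches$end[i]
      }
    }
  }
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
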