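# Planted-motif promoter simulator.
#
# Generates GC-controlled i.i.d. random promoter backgrounds and splices
# concrete HSE instances of known class, substitution load and insertion
# layout into them at known positions, together with a truth table, so
# scanner recall and accounting can be audited without external data.

truth_ins_total <- function(truth) sum(nchar(truth$ins_plan))
truth_width <- function(truth) 5L * truth$n_units + truth_ins_total(truth)

#' Construct a planted-motif ground-truth record
#'
#' Describes one HSE instance to be planted: where it goes, its unit
#' count and first-unit orientation, which core positions are substituted
#' (and with what base), and what is inserted in each inter-unit gap.
#' The plan must be consistent with `expected_class` under
#' [classify_hse()].
#'
#' @param record_id Identifier of the record the motif is planted in.
#' @param position 0-based offset of the motif's first base.
#' @param n_units 2 or 3.
#' @param first_orientation `"GAA_type"` or `"TTC_type"`.
#' @param sub_plan Data frame with columns `unit`, `core_pos`, `base`
#'   (replacement base, must differ from the consensus at that position),
#'   or `NULL` for none.
#' @param ins_plan Character vector of length `n_units - 1`: the bases
#'   inserted in each gap (`""` for none).
#' @param expected_class Class label the planted instance must realize.
#' @return An object of class `hse_planted_truth`.
#' @export
planted_truth <- function(record_id, position, n_units, first_orientation,
                          sub_plan = NULL, ins_plan = NULL,
                          expected_class) {
  n_units <- as.integer(n_units)
  if (!n_units %in% c(2L, 3L)) stop("n_units must be 2 or 3", call. = FALSE)
  if (!first_orientation %in% c("GAA_type", "TTC_type")) {
    stop("first_orientation must be GAA_type or TTC_type", call. = FALSE)
  }
  if (is.null(sub_plan)) {
    sub_plan <- data.frame(unit = integer(), core_pos = integer(),
                           base = character(), stringsAsFactors = FALSE)
  }
  ins_plan <- as.character(ins_plan %||% rep("", n_units - 1L))
  if (length(ins_plan) != n_units - 1L) {
    stop("ins_plan must have one entry per inter-unit gap", call. = FALSE)
  }
  orients <- unit_orientations(first_orientation, n_units)
  if (nrow(sub_plan)) {
    sub_plan <- sub_plan[order(sub_plan$unit, sub_plan$core_pos), ,
                         drop = FALSE]
    rownames(sub_plan) <- NULL
    if (anyDuplicated(sub_plan[c("unit", "core_pos")])) {
      stop("sub_plan assigns one core position twice", call. = FALSE)
    }
    for (i in seq_len(nrow(sub_plan))) {
      u <- sub_plan$unit[i]; p <- sub_plan$core_pos[i]
      if (u < 1L || u > n_units || p < 1L || p > 3L) {
        stop("sub_plan entry outside the unit/core grid", call. = FALSE)
      }
      cons <- core_bases(orients[u])[p]
      if (!sub_plan$base[i] %in% c("A", "C", "G", "T", "N") ||
          sub_plan$base[i] == cons) {
        stop("sub_plan base must be a valid base differing from the ",
             "consensus '", cons, "'", call. = FALSE)
      }
    }
  }
  if (any(grepl("[^ACGTN]", ins_plan))) {
    stop("ins_plan bases must be over A/C/G/T/N", call. = FALSE)
  }
  got <- classify_hse(n_units, nrow(sub_plan), sum(nchar(ins_plan)))
  if (!identical(got, expected_class)) {
    stop("plan realizes class '", got, "', not expected_class '",
         expected_class, "'", call. = FALSE)
  }
  structure(list(record_id = as.character(record_id),
                 position = as.integer(position), n_units = n_units,
                 first_orientation = first_orientation,
                 sub_plan = sub_plan, ins_plan = ins_plan,
                 expected_class = expected_class),
            class = "hse_planted_truth")
}

#' Sample a random promoter background
#'
#' Draws an i.i.d. DNA sequence with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`. Identical arguments give
#' identical sequences. When `forbid_matches_under` is supplied, the draw
#' is rejection-sampled (audited with [oracle_scan()]) until the sequence
#' contains no match under that envelope.
#'
#' @param length Sequence length (>= 1).
#' @param gc_fraction GC content in `[0, 1]`.
#' @param seed Integer seed.
#' @param forbid_matches_under Optional [scan_params()] envelope or preset
#'   name the background must be free of.
#' @param max_attempts Rejection-sampling cap; exhaustion is an error.
#' @return DNA string.
#' @export
sample_background <- function(length, gc_fraction, seed,
                              forbid_matches_under = NULL,
                              max_attempts = 100L) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1",
                                         call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      s <- paste(sample(names(probs), length, replace = TRUE,
                        prob = probs), collapse = "")
      if (is.null(forbid_matches_under)) return(s)
      hits <- oracle_scan(promoter_record("background", s),
                          forbid_matches_under)$matches
      if (nrow(hits) == 0L) return(s)
    }
    stop("no motif-free background found in ", max_attempts,
         " attempts; loosen the forbidden envelope or shorten the ",
         "sequence", call. = FALSE)
  })
}

#' Splice a planted HSE into a background
#'
#' Overwrites the `5 * n_units` unit-footprint bases at the planting
#' position with the concrete motif (wildcard positions keep the
#' background base they overwrite; core positions take the consensus or
#' the planned substitution) and inserts the planned gap bases between
#' units, so the sequence grows by exactly the motif's internal
#' insertions.
#'
#' @param background DNA string.
#' @param truth An [planted_truth()] object; its footprint must fit.
#' @return The modified DNA string.
#' @export
embed_hse <- function(background, truth) {
  stopifnot(inherits(truth, "hse_planted_truth"))
  n <- truth$n_units
  pos <- truth$position
  L <- nchar(background)
  if (pos < 0L || pos + 5L * n > L) {
    stop("planted footprint [", pos, ", ", pos + 5L * n,
         ") exceeds the background (length ", L, ")", call. = FALSE)
  }
  bgc <- strsplit(background, "")[[1]]
  orients <- unit_orientations(truth$first_orientation, n)
  pieces <- character(0)
  for (k in seq_len(n)) {
    fp <- pos + (k - 1L) * 5L + 1:5  # 1-based footprint of unit k
    core <- core_bases(orients[k])
    sel <- truth$sub_plan[truth$sub_plan$unit == k, , drop = FALSE]
    if (nrow(sel)) core[sel$core_pos] <- sel$base
    pieces <- c(pieces, bgc[fp[1]], core, bgc[fp[5]])
    if (k < n) pieces <- c(pieces, truth$ins_plan[k])
  }
  paste0(substr(background, 1L, pos), paste(pieces, collapse = ""),
         substring(background, pos + 5L * n + 1L))
}

# Deterministic class allocation: exact largest-remainder counts, dealt
# round-robin so consecutive truths cycle through the classes.
allocate_classes <- function(class_mix, total) {
  if (is.list(class_mix)) class_mix <- unlist(class_mix)
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% hse_classes)) {
    stop("class_mix must be named with HSE class labels", call. = FALSE)
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  counts <- floor(class_mix * total)
  rem <- total - sum(counts)
  if (rem > 0) {
    frac <- class_mix * total - counts
    top <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  seqv <- rep(names(class_mix), counts)
  within <- stats::ave(seq_along(seqv), seqv, FUN = seq_along)
  seqv[order(within, match(seqv, names(class_mix)))]
}

# Draw a random degeneracy plan realizing `class` with the current RNG.
draw_truth_plan <- function(class) {
  n <- if (class %in% c("canonical", "imperfect_triple")) 3L else 2L
  max_subs <- switch(class, canonical = 0L, minimal_perfect = 0L,
                     imperfect_triple = 2L, imperfect_minimal = 1L)
  first <- sample(c("GAA_type", "TTC_type"), 1L)
  orients <- unit_orientations(first, n)
  if (max_subs == 0L) {
    subs <- 0L; ins <- 0L
  } else {
    pairs <- expand.grid(subs = 0:max_subs, ins = 0:2)
    pairs <- pairs[pairs$subs + pairs$ins > 0L, , drop = FALSE]
    i <- sample(nrow(pairs), 1L)
    subs <- pairs$subs[i]; ins <- pairs$ins[i]
  }
  sub_plan <- NULL
  if (subs > 0L) {
    ids <- sort(sample(3L * n, subs))
    sub_plan <- data.frame(
      unit = (ids - 1L) %/% 3L + 1L,
      core_pos = (ids - 1L) %% 3L + 1L,
      stringsAsFactors = FALSE)
    sub_plan$base <- vapply(seq_len(nrow(sub_plan)), function(i) {
      cons <- core_bases(orients[sub_plan$unit[i]])[sub_plan$core_pos[i]]
      sample(setdiff(c("A", "C", "G", "T"), cons), 1L)
    }, "")
  }
  gap_lens <- if (n == 2L) ins else {
    vecs <- expand.grid(g1 = 0:2, g2 = 0:2)
    vecs <- vecs[vecs$g1 + vecs$g2 == ins, , drop = FALSE]
    as.integer(vecs[sample(nrow(vecs), 1L), ])
  }
  ins_plan <- vapply(gap_lens, function(g) {
    paste(sample(c("A", "C", "G", "T"), g, replace = TRUE), collapse = "")
  }, "")
  list(n_units = n, first_orientation = first, sub_plan = sub_plan,
       ins_plan = ins_plan, expected_class = class)
}

format_sub_plan <- function(sub_plan) {
  if (is.null(sub_plan) || nrow(sub_plan) == 0L) return(".")
  paste(sprintf("u%dp%d=%s", sub_plan$unit, sub_plan$core_pos,
                sub_plan$base), collapse = ",")
}

format_ins_plan <- function(ins_plan) {
  nz <- which(nchar(ins_plan) > 0L)
  if (length(nz) == 0L) return(".")
  paste(sprintf("g%d=%s", nz, ins_plan[nz]), collapse = ",")
}

# Audit one planted truth against the record with the brute-force oracle:
# the canonical alignment at the planted span must reproduce the plan.
truth_recovered <- function(rec, truth, pos_final) {
  m <- oracle_scan(rec, truth$expected_class)$matches
  w <- truth_width(truth)
  gap <- format_gap_vector(nchar(truth$ins_plan))
  subp <- if (nrow(truth$sub_plan)) {
    format_sub_positions(truth$sub_plan$unit, truth$sub_plan$core_pos)
  } else "."
  any(m$start == pos_final & m$end == pos_final + w &
        m$first_unit_orientation == truth$first_orientation &
        m$substitutions_total == nrow(truth$sub_plan) &
        m$substitution_positions == subp &
        m$insertions_per_gap == gap &
        m$class == truth$expected_class)
}

#' Generate a planted-motif benchmark
#'
#' Writes a multi-record FASTA of random promoter backgrounds with HSE
#' instances of the requested class mix planted at known, non-overlapping
#' positions, plus a tab-delimited truth table (one row per planted
#' motif, final 0-based coordinates). Fully reproducible from the seed.
#' Each record is audited with the brute-force oracle before acceptance:
#' the canonical alignment at every planted span must reproduce the
#' planted substitution and insertion accounting exactly (records where
#' random context would alias a plan to a cheaper alignment are redrawn).
#'
#' @param n_records Number of records.
#' @param record_length Background length before insertions.
#' @param truths_per_record Planted motifs per record.
#' @param class_mix Named proportions over [hse_classes]; must sum to 1.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param gc_fraction Background GC content.
#' @param margin Minimum spacing between planted footprints, bp.
#' @param max_attempts Per-record redraw cap.
#' @return Invisibly, a list with `fasta`, `truth_table` (file paths),
#'   `promoters` (record frame) and `truths` (truth data frame).
#' @export
generate_benchmark <- function(n_records, record_length,
                               truths_per_record, class_mix, seed,
                               out_dir, gc_fraction = 0.5, margin = 3L,
                               max_attempts = 60L) {
  classes <- allocate_classes(class_mix, n_records * truths_per_record)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- sprintf("synrec%03d", seq_len(n_records))
  seqs <- character(n_records)
  truth_rows <- list()
  for (i in seq_len(n_records)) {
    cls <- classes[(i - 1L) * truths_per_record + seq_len(truths_per_record)]
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      aseed <- derive_seed(seed, i * 1000L + attempt)
      bg <- sample_background(record_length, gc_fraction, aseed)
      placed <- with_seed(aseed + 1L, {
        plans <- lapply(cls, draw_truth_plan)
        taken <- matrix(numeric(0), ncol = 2)
        positions <- integer(length(plans))
        ok <- TRUE
        for (t in seq_along(plans)) {
          fp <- 5L * plans[[t]]$n_units
          hit <- FALSE
          for (try in 1:300) {
            p <- sample(0:(record_length - fp), 1L)
            lo <- p - margin; hi <- p + fp + margin
            if (nrow(taken) == 0L ||
                all(hi <= taken[, 1] | lo >= taken[, 2])) {
              taken <- rbind(taken, c(lo, hi))
              positions[t] <- p
              hit <- TRUE
              break
            }
          }
          if (!hit) { ok <- FALSE; break }
        }
        if (ok) list(plans = plans, positions = positions) else NULL
      })
      if (is.null(placed)) next
      ord <- order(placed$positions)
      plans <- placed$plans[ord]
      positions <- placed$positions[ord]
      ins_lens <- vapply(plans, function(p) sum(nchar(p$ins_plan)), 0L)
      shifts <- c(0L, cumsum(ins_lens))[seq_along(plans)]
      final_pos <- positions + shifts
      truths <- lapply(seq_along(plans), function(t) {
        planted_truth(ids[i], positions[t], plans[[t]]$n_units,
                      plans[[t]]$first_orientation, plans[[t]]$sub_plan,
                      plans[[t]]$ins_plan, plans[[t]]$expected_class)
      })
      s <- bg
      for (t in rev(seq_along(truths))) s <- embed_hse(s, truths[[t]])
      rec <- promoter_record(ids[i], s)
      if (all(vapply(seq_along(truths), function(t) {
        truth_recovered(rec, truths[[t]], final_pos[t])
      }, logical(1)))) {
        seqs[i] <- s
        for (t in seq_along(truths)) {
          tr <- truths[[t]]
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            record_id = ids[i], position = final_pos[t],
            n_units = tr$n_units,
            first_orientation = tr$first_orientation,
            width = truth_width(tr),
            substitutions_total = nrow(tr$sub_plan),
            sub_plan = format_sub_plan(tr$sub_plan),
            insertions_total = truth_ins_total(tr),
            ins_plan = format_ins_plan(tr$ins_plan),
            expected_class = tr$expected_class,
            stringsAsFactors = FALSE)
        }
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("could not place and verify the requested truths for record ",
           ids[i], " in ", max_attempts, " attempts", call. = FALSE)
    }
  }
  fasta <- file.path(out_dir, "benchmark.fasta")
  truth_path <- file.path(out_dir, "benchmark_truth.tsv")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)), fasta,
    width = 70L)
  truths <- do.call(rbind, truth_rows)
  rownames(truths) <- NULL
  utils::write.table(truths, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, truth_table = truth_path,
                 promoters = do.call(rbind, lapply(seq_along(ids),
                   function(i) promoter_record(ids[i], seqs[i]))),
                 truths = truths))
}
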