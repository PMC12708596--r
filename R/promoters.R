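# Promoter record input: FASTA reading, TSS sidecar resolution, validation.

validate_sequence <- function(sequence, record_id) {
  bad <- regexpr("[^ACGTNacgtn]", sequence)[1]
  if (bad > 0L) {
    stop(sprintf(
      "record '%s': invalid character '%s' at position %d (alphabet is A/C/G/T/N)",
      record_id, substr(sequence, bad, bad), bad), call. = FALSE)
  }
  toupper(sequence)
}

#' Construct a promoter record
#'
#' A promoter record holds one promoter sequence on its sense strand
#' (5'->3'), its identifier, and the 0-based offset of the transcription
#' start site (TSS). When the record is a pure upstream fragment the TSS
#' is one past the last promoter base, which is the default when `tss`
#' is not supplied.
#'
#' @param record_id Identifier, unique within one input set.
#' @param sequence DNA string over A/C/G/T/N; lowercase is uppercased.
#' @param tss 0-based TSS offset in `[0, nchar(sequence)]`; default is the
#'   sequence length (TSS immediately downstream of the fragment).
#' @return A one-row data frame with columns `record_id`, `sequence`,
#'   `tss`, `length`.
#' @export
promoter_record <- function(record_id, sequence, tss = NULL) {
  sequence <- validate_sequence(sequence, record_id)
  len <- nchar(sequence)
  tss <- as.integer(tss %||% len)
  if (is.na(tss) || tss < 0L || tss > len) {
    stop(sprintf("record '%s': tss must lie in [0, %d]", record_id, len),
         call. = FALSE)
  }
  data.frame(record_id = as.character(record_id), sequence = sequence,
             tss = tss, length = len, stringsAsFactors = FALSE)
}

as_promoter_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L) {
      stop("expected a single promoter record", call. = FALSE)
    }
    record <- as.list(record)
  }
  stopifnot(!is.null(record$record_id), !is.null(record$sequence))
  if (is.null(record$tss)) record$tss <- nchar(record$sequence)
  if (is.null(record$length)) record$length <- nchar(record$sequence)
  record
}

read_tss_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(data.frame(record_id = character(),
                                             value = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) {
    stop("TSS sidecar line ", bad[1],
         " does not have two tab-separated columns", call. = FALSE)
  }
  data.frame(record_id = vapply(parts, `[[`, "", 1L),
             value = trimws(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Read promoter sequences and TSS annotations
#'
#' Reads a multi-record FASTA file of promoter sequences (wrapped or
#' unwrapped) into validated promoter records. An optional tab-delimited
#' sidecar table maps record IDs to 1-based TSS positions (or the literal
#' token `"end"` for the position one past the last base); records absent
#' from the sidecar default to TSS = sequence end. `#`-prefixed sidecar
#' lines are ignored.
#'
#' @param fasta_path Path to a FASTA file (DNA over A/C/G/T/N).
#' @param tss_table_path Optional path to the two-column TSS sidecar.
#' @return Data frame of promoter records (columns `record_id`,
#'   `sequence`, `tss`, `length`), in input order. TSS offsets are 0-based.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACGT", ">p2", "GGAA"), fa)
#' read_promoters(fa)
#' @export
read_promoters <- function(fasta_path, tss_table_path = NULL) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  xs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(xs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate record ID in FASTA: '", dup[1], "'", call. = FALSE)
  }
  seqs <- as.character(xs)
  recs <- do.call(rbind, lapply(seq_along(ids), function(i) {
    promoter_record(ids[i], seqs[i])
  }))
  if (!is.null(tss_table_path)) {
    if (!file.exists(tss_table_path)) {
      stop("TSS table not found: ", tss_table_path, call. = FALSE)
    }
    tab <- read_tss_table(tss_table_path)
    for (i in seq_len(nrow(tab))) {
      id <- tab$record_id[i]
      j <- match(id, recs$record_id)
      if (is.na(j)) {
        stop("TSS sidecar names record '", id,
             "' which is absent from the FASTA", call. = FALSE)
      }
      val <- tab$value[i]
      if (identical(val, "end")) {
        recs$tss[j] <- recs$length[j]
      } else {
        pos <- suppressWarnings(as.integer(val))
        if (is.na(pos) || pos < 1L || pos > recs$length[j]) {
          stop(sprintf(
            "record '%s': sidecar TSS '%s' outside [1, %d]",
            id, val, recs$length[j]), call. = FALSE)
        }
        recs$tss[j] <- pos - 1L  # 1-based sidecar -> 0-based internal
      }
    }
  }
  rownames(recs) <- NULL
  recs
}
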