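# BUSCO full_table dialects. v5 writes
#   "# Busco id  Status  Sequence  Gene Start  Gene End  Strand  Score  Length"
# (tab-separated); v3/v4 write "Busco id  Status  Contig  Start  End  Score
# Length" with no Strand column. Some older runs embed coordinates in the
# sequence field as "scaffold:start-end".

.busco_statuses <- c("Complete", "Duplicated", "Fragmented", "Missing")

.canon_col <- function(x) gsub("[^a-z]", "", tolower(x))

.busco_col_map <- function(header_fields) {
  cn <- .canon_col(header_fields)
  find <- function(keys) {
    i <- which(cn %in% keys)
    if (length(i)) i[1] else NA_integer_
  }
  list(
    marker_id = find(c("buscoid", "busco")),
    status    = find("status"),
    sequence  = find(c("sequence", "contig", "scaffold")),
    start     = find(c("genestart", "start")),
    end       = find(c("geneend", "end", "stop")),
    strand    = find("strand"),
    score     = find("score"),
    length    = find(c("length", "genelength"))
  )
}

# Positional fallback when no recognizable header line is present (v5 order).
.busco_v5_positions <- list(
  marker_id = 1L, status = 2L, sequence = 3L, start = 4L, end = 5L,
  strand = 6L, score = 7L, length = 8L
)

#' Parse a BUSCO full table
#'
#' Reads the text of a BUSCO `full_table.tsv` into a tibble of marker
#' records, one row per table line. Duplicated markers therefore keep all
#' of their lines; filtering is a separate, explicit step
#' ([filter_usable()]). The column layout is detected from the commented
#' header: version 5 tables carry a `Strand` column, version 3/4 tables do
#' not, in which case every record gets `strand = "unknown"`. When no
#' `Gene Start` column exists but the sequence field looks like
#' `"scaffold:start-end"`, coordinates are recovered from that pattern.
#'
#' Coordinates are 1-based inclusive. Only the relative order of markers is
#' used downstream, so the off-by-one convention cannot change any result.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @return A tibble with columns `marker_id`, `status` (one of Complete,
#'   Duplicated, Fragmented, Missing), `sequence_id`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"unknown"`), `score`, `length`. Missing
#'   markers have `NA` position fields. Input order is preserved. The
#'   detected dialect is stored in `attr(, "dialect")`.
#' @seealso [read_full_table()] to read from a file path,
#'   [write_full_table()] for the inverse.
#' @export
#' @examples
#' tab <- c(
#'   "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength",
#'   "1at7088\tComplete\tChr1\t100\t900\t+\t500.1\t700",
#'   "2at7088\tMissing"
#' )
#' parse_full_table(tab)
parse_full_table <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  is_comment <- startsWith(lines, "#")
  header_idx <- which(is_comment & grepl("usco", lines) & grepl("\t", lines, fixed = TRUE))
  if (length(header_idx)) {
    header <- strsplit(sub("^#\\s*", "", lines[header_idx[1]]), "\t", fixed = TRUE)[[1]]
    cols <- .busco_col_map(header)
    if (is.na(cols$marker_id) || is.na(cols$status)) cols <- .busco_v5_positions
  } else {
    cols <- .busco_v5_positions
  }
  dialect <- if (is.na(cols$strand)) "v3/v4" else "v5"

  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(data_idx)) {
    out <- tibble::tibble(
      marker_id = character(), status = character(), sequence_id = character(),
      start = numeric(), end = numeric(), strand = character(),
      score = numeric(), length = numeric()
    )
    attr(out, "dialect") <- dialect
    return(out)
  }

  parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  field <- function(i) {
    if (is.na(i)) return(rep(NA_character_, length(parts)))
    vapply(parts, function(p) if (i <= length(p)) p[[i]] else NA_character_, character(1))
  }
  blank_to_na <- function(x) replace(x, !is.na(x) & !nzchar(trimws(x)), NA_character_)

  marker_id <- blank_to_na(field(cols$marker_id))
  status <- blank_to_na(field(cols$status))
  bad <- is.na(marker_id) | is.na(status)
  if (any(bad)) {
    stop("malformed line ", data_idx[which(bad)[1]],
         ": expected at least a marker id and a status", call. = FALSE)
  }
  unknown <- !status %in% .busco_statuses
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("line ", data_idx[i], ": unrecognized status \"", status[i], "\"",
         call. = FALSE)
  }

  present <- status != "Missing"
  sequence_id <- blank_to_na(field(cols$sequence))
  start_chr <- blank_to_na(field(cols$start))
  end_chr <- blank_to_na(field(cols$end))

  if (any(present & is.na(sequence_id))) {
    i <- which(present & is.na(sequence_id))[1]
    stop("malformed line ", data_idx[i],
         ": wrong column count (no sequence for a placed marker)", call. = FALSE)
  }

  if (is.na(cols$start)) {
    # Older dialect embedding coordinates in the sequence field.
    m <- stringr::str_match(sequence_id, "^(.*):([0-9]+)-([0-9]+)$")
    emb <- present & !is.na(m[, 1])
    sequence_id[emb] <- m[emb, 2]
    start_chr[emb] <- m[emb, 3]
    end_chr[emb] <- m[emb, 4]
  } else if (any(present & is.na(start_chr))) {
    i <- which(present & is.na(start_chr))[1]
    stop("malformed line ", data_idx[i],
         ": wrong column count (no coordinates for a placed marker)",
         call. = FALSE)
  }

  to_coord <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- present & !is.na(x) & is.na(out)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("line ", data_idx[i], ": non-integer ", what, " coordinate \"",
           x[i], "\"", call. = FALSE)
    }
    out
  }
  start <- to_coord(start_chr, "start")
  end <- to_coord(end_chr, "end")
  flipped <- present & !is.na(start) & !is.na(end) & start > end
  if (any(flipped)) {
    i <- which(flipped)[1]
    stop("line ", data_idx[i], ": start > end", call. = FALSE)
  }

  strand <- field(cols$strand)
  strand <- ifelse(is.na(strand) | !strand %in% c("+", "-"), "unknown", strand)
  score <- suppressWarnings(as.numeric(blank_to_na(field(cols$score))))
  len <- suppressWarnings(as.numeric(blank_to_na(field(cols$length))))

  # Missing markers carry no positional information whatever the line says.
  sequence_id[!present] <- NA_character_
  start[!present] <- NA_real_
  end[!present] <- NA_real_
  strand[!present] <- "unknown"
  score[!present] <- NA_real_
  len[!present] <- NA_real_

  out <- tibble::tibble(
    marker_id = marker_id, status = status, sequence_id = sequence_id,
    start = start, end = end, strand = strand, score = score, length = len
  )
  attr(out, "dialect") <- dialect
  out
}

#' @rdname parse_full_table
#' @param file Path to a `full_table.tsv`.
#' @export
read_full_table <- function(file) {
  parse_full_table(readLines(file, warn = FALSE))
}

#' Serialize marker records as a BUSCO v5 full table
#'
#' The inverse of [parse_full_table()]: emits a version-5 dialect table such
#' that re-parsing reproduces the records field for field. Missing markers
#' are written as two-column lines; absent strand/score/length fields are
#' written as empty columns. Score and Length are unused by the synteny
#' method but retained for round-trip fidelity.
#'
#' @param records A marker-record tibble as returned by [parse_full_table()].
#' @param file Optional path; when given, the lines are written there.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
write_full_table <- function(records, file = NULL) {
  .check_records(records)
  fmt_num <- function(x) {
    out <- rep("", length(x))
    ok <- !is.na(x)
    out[ok] <- format(x[ok], scientific = FALSE, trim = TRUE)
    out
  }
  header <- "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength"
  if (nrow(records) == 0) {
    out <- header
  } else {
    miss <- records$status == "Missing"
    strand <- ifelse(records$strand %in% c("+", "-"), records$strand, "")
    body <- ifelse(
      miss,
      paste(records$marker_id, records$status, sep = "\t"),
      paste(records$marker_id, records$status,
            ifelse(is.na(records$sequence_id), "", records$sequence_id),
            fmt_num(records$start), fmt_num(records$end), strand,
            fmt_num(records$score), fmt_num(records$length),
            sep = "\t")
    )
    out <- c(header, body)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.check_records <- function(records) {
  need <- c("marker_id", "status", "sequence_id", "start", "end", "strand")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("`records` must be a marker-record tibble (see parse_full_table())",
         call. = FALSE)
  }
  invisible(records)
}

#' Read a sequence-length table
#'
#' Reads any tab-separated table whose first two columns are sequence name
#' and length in bp -- a samtools `.fai` index qualifies. Lengths are the
#' denominators for per-Mbp rearrangement rates.
#'
#' @param file Path to the table.
#' @param text Character vector of lines (alternative to `file`).
#' @return A tibble with columns `sequence_id` and `length`;
#'   `attr(, "inferred")` is `FALSE` to mark the lengths as supplied.
#' @seealso [infer_sequence_lengths()] for the fallback when no index is
#'   available.
#' @export
load_sequence_lengths <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 2
  if (any(short)) {
    stop("sequence-length table line ", which(short)[1],
         ": expected at least 2 tab-separated columns", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(len) || any(len <= 0)) {
    i <- which(is.na(len) | len <= 0)[1]
    stop("sequence \"", ids[i], "\": length must be a positive number",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence name \"", ids[anyDuplicated(ids)], "\"",
         call. = FALSE)
  }
  out <- tibble::tibble(sequence_id = ids, length = len)
  attr(out, "inferred") <- FALSE
  out
}

#' Infer sequence lengths from marker coordinates
#'
#' When no FASTA index is supplied, the end coordinate of the last marker on
#' each sequence gives a lower bound on its length. Rates computed on such
#' lengths are flagged as inferred (and are therefore slight overestimates).
#'
#' @param records A marker-record tibble; at least one record must carry
#'   coordinates.
#' @return A tibble with columns `sequence_id` and `length`;
#'   `attr(, "inferred")` is `TRUE`.
#' @export
infer_sequence_lengths <- function(records) {
  .check_records(records)
  pos <- records[!is.na(records$sequence_id) & !is.na(records$start), ]
  if (nrow(pos) == 0) {
    stop("no positioned records to infer sequence lengths from", call. = FALSE)
  }
  hi <- pmax(pos$end, pos$start, na.rm = TRUE)
  out <- pos |>
    dplyr::mutate(.hi = hi) |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::summarise(length = max(.data$.hi), .groups = "drop")
  out <- tibble::as_tibble(out)
  attr(out, "inferred") <- TRUE
  out
}
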