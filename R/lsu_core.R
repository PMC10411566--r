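#' Filter a marker table down to usable single-copy records
#'
#' Discards every `Missing` record and every line of any marker that occurs
#' with status `Duplicated` (all copies are dropped, not just the extras:
#' BUSCO cannot say which copy is the orthologous one). `Fragmented`
#' records are kept by default and can be dropped with `drop_fragmented`.
#'
#' @param records A marker-record tibble ([parse_full_table()]).
#' @param drop_fragmented Also discard `Fragmented` records.
#' @param quiet Suppress the message reporting removal counts.
#' @return The retained records, in their original relative order.
#' @export
filter_usable <- function(records, drop_fragmented = FALSE, quiet = FALSE) {
  .check_records(records)
  dup_ids <- unique(records$marker_id[records$status == "Duplicated"])
  keep <- records$status != "Missing" & !records$marker_id %in% dup_ids
  n_missing <- sum(records$status == "Missing")
  n_dup <- sum(records$status != "Missing" & records$marker_id %in% dup_ids)
  n_frag <- 0L
  if (drop_fragmented) {
    n_frag <- sum(keep & records$status == "Fragmented")
    keep <- keep & records$status != "Fragmented"
  }
  out <- records[keep, ]
  if (nrow(out) == 0) stop("no usable markers after filtering", call. = FALSE)
  if (!quiet) {
    message(sprintf(
      "retained %d of %d marker lines (removed %d Missing, %d Duplicated%s)",
      nrow(out), nrow(records), n_missing, n_dup,
      if (drop_fragmented) sprintf(", %d Fragmented", n_frag) else ""
    ))
  }
  out
}

# Order sequence names so that numeric suffixes sort numerically and any
# Z-named sequence goes last (the Z chromosome's unit gets the highest
# index). Names without a numeric suffix sort after numbered ones,
# alphabetically.
.order_sequences_suffix <- function(seq_names) {
  num <- suppressWarnings(as.numeric(stringr::str_match(seq_names, "([0-9]+)$")[, 2]))
  is_z <- grepl("[Zz]$", seq_names)
  key_num <- ifelse(is.na(num), Inf, num)
  seq_names[order(is_z, key_num, seq_names)]
}

.positioned <- function(records, quiet = FALSE) {
  pos <- !is.na(records$sequence_id) & !is.na(records$start)
  if (!all(pos) && !quiet) {
    message(sum(!pos), " record(s) without coordinates dropped")
  }
  records[pos, ]
}

#' Define synteny units from an anchor genome
#'
#' Groups the anchor genome's usable markers by chromosome and orders them
#' by position; each chromosome-specific marker subset becomes one synteny
#' unit (`LSU_1` ... `LSU_n`). This is the anchor table against which all
#' target genomes are compared. With the canonical 31-chromosome
#' lepidopteran anchor, the Z chromosome's subset becomes the last unit.
#'
#' @param records Filtered anchor records ([filter_usable()]); they must
#'   carry coordinates.
#' @param naming_policy How unit numbers follow anchor chromosomes:
#'   `"by_sequence_suffix"` (default) extracts trailing integers from
#'   chromosome names and puts Z-named sequences last; `"by_length_desc"`
#'   numbers by decreasing chromosome length (requires `lengths`);
#'   `"as_encountered"` follows input order.
#' @param lengths Optional sequence-length tibble
#'   ([load_sequence_lengths()]), required for `"by_length_desc"`.
#' @param anchor_name Label recorded for the anchor genome.
#' @return A tibble of class `lsu_table` with columns `lsu_id`,
#'   `marker_id`, `anchor_sequence`, `anchor_start`, `anchor_rank` (the
#'   marker's 1-based position rank within its unit). Attributes:
#'   `anchor_name`, `lsu_names` (ordered unit ids), `lsu_map` (named map
#'   anchor sequence -> unit id).
#' @export
define_lsus <- function(records,
                        naming_policy = c("by_sequence_suffix", "by_length_desc",
                                          "as_encountered"),
                        lengths = NULL, anchor_name = "anchor") {
  naming_policy <- match.arg(naming_policy)
  .check_records(records)
  pos <- .positioned(records)
  if (nrow(pos) == 0) stop("no records with coordinates", call. = FALSE)
  if (anyDuplicated(pos$marker_id)) {
    dup <- unique(pos$marker_id[duplicated(pos$marker_id)])
    stop("marker(s) occur more than once after filtering: ",
         paste(head(dup, 3), collapse = ", "),
         " ... run filter_usable() (possibly with drop_fragmented = TRUE)",
         call. = FALSE)
  }

  seqs <- unique(pos$sequence_id)
  if (length(seqs) < 2) {
    warning("fewer than 2 marker-bearing sequences; units defined anyway",
            call. = FALSE)
  }
  seq_order <- switch(naming_policy,
    by_sequence_suffix = .order_sequences_suffix(seqs),
    by_length_desc = {
      if (is.null(lengths)) {
        stop("naming_policy \"by_length_desc\" requires `lengths`", call. = FALSE)
      }
      known <- lengths$sequence_id[order(-lengths$length)]
      c(known[known %in% seqs], setdiff(seqs, known))
    },
    as_encountered = seqs
  )
  lsu_names <- paste0("LSU_", seq_along(seq_order))
  lsu_map <- stats::setNames(lsu_names, seq_order)

  ord <- order(match(pos$sequence_id, seq_order), pos$start, pos$end, pos$marker_id)
  pos <- pos[ord, ]
  out <- tibble::tibble(
    lsu_id = unname(lsu_map[pos$sequence_id]),
    marker_id = pos$marker_id,
    anchor_sequence = pos$sequence_id,
    anchor_start = pos$start,
    anchor_rank = stats::ave(pos$start, pos$sequence_id, FUN = seq_along)
  )
  attr(out, "anchor_name") <- anchor_name
  attr(out, "lsu_names") <- lsu_names
  attr(out, "lsu_map") <- lsu_map
  class(out) <- c("lsu_table", class(out))
  out
}

#' Summarize marker coverage of anchor chromosomes
#'
#' Per-chromosome marker count and the span from the first marker position
#' to the end of the last marker, optionally with chromosome sizes when a
#' length table is supplied.
#'
#' @inheritParams define_lsus
#' @return A tibble with columns `sequence_id`, `size_bp` (`NA` without
#'   `lengths`), `from_pos`, `to_pos`, `n_markers`, ordered like the unit
#'   numbering.
#' @export
coverage_summary <- function(records, lengths = NULL) {
  .check_records(records)
  pos <- .positioned(records, quiet = TRUE)
  if (nrow(pos) == 0) stop("no records with coordinates", call. = FALSE)
  hi <- pmax(pos$end, pos$start, na.rm = TRUE)
  out <- pos |>
    dplyr::mutate(.hi = hi) |>
    dplyr::group_by(sequence_id = .data$sequence_id) |>
    dplyr::summarise(
      from_pos = min(.data$start),
      to_pos = max(.data$.hi),
      n_markers = dplyr::n(),
      .groups = "drop"
    )
  out$size_bp <- if (!is.null(lengths)) {
    lengths$length[match(out$sequence_id, lengths$sequence_id)]
  } else {
    NA_real_
  }
  out <- out[match(.order_sequences_suffix(out$sequence_id), out$sequence_id),
             c("sequence_id", "size_bp", "from_pos", "to_pos", "n_markers")]
  tibble::as_tibble(out)
}

#' Assign target-genome markers to synteny units
#'
#' Joins a target genome's usable markers to the anchor's unit table by
#' marker identity alone -- positions are never compared across genomes.
#' Rows are ordered along the target chromosomes and ranked by position, so
#' downstream steps can read marker order directly.
#'
#' @param target_records Filtered target records ([filter_usable()]).
#' @param lsu_table An `lsu_table` from [define_lsus()].
#' @param target_name Label recorded for the target genome.
#' @param quiet Suppress the message reporting unassigned markers.
#' @return A tibble of class `lsu_assignment` with columns `marker_id`,
#'   `lsu_id` (`NA` for markers absent from the unit table),
#'   `target_sequence`, `target_start`, `target_rank` (1-based position
#'   rank within each target sequence), `anchor_rank`. Attributes:
#'   `target_name`, `anchor_name`, `lsu_names`, `n_unassigned`.
#' @export
assign_markers <- function(target_records, lsu_table, target_name = "target",
                           quiet = FALSE) {
  if (!inherits(lsu_table, "lsu_table")) {
    stop("`lsu_table` must come from define_lsus() or read_lsu_table()",
         call. = FALSE)
  }
  .check_records(target_records)
  pos <- .positioned(target_records, quiet = quiet)
  if (anyDuplicated(pos$marker_id)) {
    stop("target markers occur more than once after filtering; ",
         "run filter_usable() first", call. = FALSE)
  }
  idx <- match(pos$marker_id, lsu_table$marker_id)
  if (all(is.na(idx))) {
    stop("no overlap between target markers and the unit table", call. = FALSE)
  }
  ord <- order(pos$sequence_id, pos$start, pos$end, pos$marker_id)
  pos <- pos[ord, ]
  idx <- idx[ord]
  out <- tibble::tibble(
    marker_id = pos$marker_id,
    lsu_id = lsu_table$lsu_id[idx],
    target_sequence = pos$sequence_id,
    target_start = pos$start,
    target_rank = stats::ave(pos$start, pos$sequence_id, FUN = seq_along),
    anchor_rank = lsu_table$anchor_rank[idx]
  )
  n_un <- sum(is.na(out$lsu_id))
  if (n_un > 0 && !quiet) {
    message(n_un, " target marker(s) not present in the unit table left unassigned")
  }
  attr(out, "target_name") <- target_name
  attr(out, "anchor_name") <- attr(lsu_table, "anchor_name")
  attr(out, "lsu_names") <- attr(lsu_table, "lsu_names")
  attr(out, "n_unassigned") <- n_un
  class(out) <- c("lsu_assignment", class(out))
  out
}

#' Tabulate unit hit counts per target chromosome
#'
#' Counts assigned markers in every (target sequence x unit) cell. The
#' resulting matrix is the raw material for fusion/split classification:
#' an unrearranged genome gives a (permuted) diagonal matrix, a fusion
#' shows as one row with two strong cells.
#'
#' @param assignment An `lsu_assignment` from [assign_markers()].
#' @return An object of class `lsu_composition`: a list with `matrix`
#'   (integer matrix, rows = target sequences, columns = units; all units
#'   of the anchor table are kept as columns even when unhit),
#'   `chromosome_calls` and `lsu_calls` (`NULL` until
#'   [classify_composition()] is run), `n_assigned`, `n_unassigned`.
#' @export
composition_matrix <- function(assignment) {
  if (!inherits(assignment, "lsu_assignment")) {
    stop("`assignment` must come from assign_markers()", call. = FALSE)
  }
  if (nrow(assignment) == 0) stop("empty assignment", call. = FALSE)
  a <- assignment[!is.na(assignment$lsu_id), ]
  seqs <- unique(assignment$target_sequence)
  lsus <- attr(assignment, "lsu_names")
  mat <- table(
    factor(a$target_sequence, levels = seqs),
    factor(a$lsu_id, levels = lsus)
  )
  mat <- matrix(as.integer(mat), nrow = length(seqs),
                dimnames = list(seqs, lsus))
  structure(
    list(
      matrix = mat,
      chromosome_calls = NULL,
      lsu_calls = NULL,
      params = NULL,
      n_assigned = nrow(a),
      n_unassigned = attr(assignment, "n_unassigned") %||% 0L,
      target_name = attr(assignment, "target_name"),
      anchor_name = attr(assignment, "anchor_name")
    ),
    class = "lsu_composition"
  )
}

#' Classify chromosome fusions and unit splits
#'
#' A unit is a *component* of a target chromosome when it contributes at
#' least `min_component_markers` markers and at least
#' `min_component_fraction` of that chromosome's assigned markers; the
#' thresholds separate genuine fusion partners from small transposed
#' fragments. Chromosomes are then `single` (one component),
#' `fusion_of_k` (k >= 2 components) or `unclassified` (none). Units are
#' `intact` when at least `intact_fraction` of their recovered markers sit
#' on one chromosome, `split` when two or more chromosomes each hold a
#' component of the unit, and `dispersed` otherwise (the pulverized-unit
#' case, where a unit is scattered in small fractions over many
#' chromosomes).
#'
#' @param x An `lsu_composition` from [composition_matrix()].
#' @param min_component_markers Minimum markers for a component (>= 1).
#' @param min_component_fraction Minimum fraction of a chromosome's
#'   assigned markers for a component, in (0, 1].
#' @param intact_fraction Minimum fraction of a unit's recovered markers on
#'   a single chromosome to call it intact, in (0, 1].
#' @return `x` with `chromosome_calls` and `lsu_calls` tibbles filled in
#'   and the thresholds recorded in `params`.
#' @export
classify_composition <- function(x, min_component_markers = 5,
                                 min_component_fraction = 0.05,
                                 intact_fraction = 0.95) {
  if (!inherits(x, "lsu_composition")) {
    stop("`x` must come from composition_matrix()", call. = FALSE)
  }
  if (min_component_markers < 1) {
    stop("`min_component_markers` must be at least 1", call. = FALSE)
  }
  for (f in c(min_component_fraction, intact_fraction)) {
    if (f <= 0 || f > 1) {
      stop("fraction thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  M <- x$matrix
  row_tot <- rowSums(M)
  frac <- M / ifelse(row_tot == 0, 1, row_tot)
  comp <- M >= min_component_markers & frac >= min_component_fraction

  chromosome_calls <- tibble::tibble(
    target_sequence = rownames(M),
    n_markers = as.integer(row_tot),
    n_components = as.integer(rowSums(comp)),
    components = vapply(seq_len(nrow(M)), function(i) {
      u <- colnames(M)[comp[i, ]]
      u <- u[order(-M[i, comp[i, ]])]
      paste(u, collapse = "+")
    }, character(1)),
    class = dplyr::case_when(
      rowSums(comp) == 1 ~ "single",
      rowSums(comp) >= 2 ~ paste0("fusion_of_", rowSums(comp)),
      TRUE ~ "unclassified"
    )
  )

  col_tot <- colSums(M)
  hit <- which(col_tot > 0)
  lsu_calls <- tibble::tibble(
    lsu_id = colnames(M)[hit],
    n_recovered = as.integer(col_tot[hit]),
    top_sequence = rownames(M)[apply(M[, hit, drop = FALSE], 2, which.max)],
    top_fraction = apply(M[, hit, drop = FALSE], 2, max) / col_tot[hit],
    n_component_sequences = as.integer(colSums(comp[, hit, drop = FALSE]))
  )
  lsu_calls$class <- dplyr::case_when(
    lsu_calls$top_fraction >= intact_fraction ~ "intact",
    lsu_calls$n_component_sequences >= 2 ~ "split",
    TRUE ~ "dispersed"
  )

  x$chromosome_calls <- chromosome_calls
  x$lsu_calls <- lsu_calls
  x$params <- list(
    min_component_markers = min_component_markers,
    min_component_fraction = min_component_fraction,
    intact_fraction = intact_fraction
  )
  x
}

#' @export
print.lsu_table <- function(x, ...) {
  cat(sprintf("Synteny unit table: %d units, %d markers (anchor: %s)\n",
              length(attr(x, "lsu_names")), nrow(x),
              attr(x, "anchor_name") %||% "?"))
  NextMethod()
}

#' @export
print.lsu_composition <- function(x, ...) {
  cat(sprintf("Unit composition: %d target sequences x %d units, %d assigned markers\n",
              nrow(x$matrix), ncol(x$matrix), x$n_assigned))
  if (!is.null(x$chromosome_calls)) {
    tab <- table(x$chromosome_calls$class)
    cat("chromosome calls:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    tab2 <- table(x$lsu_calls$class)
    cat("unit calls:      ", paste(names(tab2), tab2, sep = "=", collapse = ", "), "\n")
  } else {
    cat("(not yet classified; run classify_composition())\n")
  }
  invisible(x)
}

#' Tidy a unit composition into long form
#'
#' @param x An `lsu_composition`.
#' @param drop_zero Drop empty (sequence, unit) cells.
#' @param ... Unused.
#' @return A tibble with `target_sequence`, `lsu_id`, `n_markers` and
#'   `fraction_of_sequence`.
#' @export
tidy.lsu_composition <- function(x, drop_zero = TRUE, ...) {
  M <- x$matrix
  out <- tibble::tibble(
    target_sequence = rep(rownames(M), times = ncol(M)),
    lsu_id = rep(colnames(M), each = nrow(M)),
    n_markers = as.integer(M)
  )
  rt <- rowSums(M)[out$target_sequence]
  out$fraction_of_sequence <- out$n_markers / ifelse(rt == 0, 1, rt)
  if (drop_zero) out <- out[out$n_markers > 0, ]
  out
}

#' One-row summary of a classified composition
#'
#' @param x A classified `lsu_composition`.
#' @param ... Unused.
#' @export
glance.lsu_composition <- function(x, ...) {
  cc <- x$chromosome_calls
  lc <- x$lsu_calls
  tibble::tibble(
    n_target_sequences = nrow(x$matrix),
    n_lsus_recovered = sum(colSums(x$matrix) > 0),
    n_assigned = x$n_assigned,
    n_unassigned = x$n_unassigned,
    n_single = if (is.null(cc)) NA_integer_ else sum(cc$class == "single"),
    n_fusion = if (is.null(cc)) NA_integer_ else sum(startsWith(cc$class, "fusion_of_")),
    n_unclassified = if (is.null(cc)) NA_integer_ else sum(cc$class == "unclassified"),
    n_intact = if (is.null(lc)) NA_integer_ else sum(lc$class == "intact"),
    n_split = if (is.null(lc)) NA_integer_ else sum(lc$class == "split"),
    n_dispersed = if (is.null(lc)) NA_integer_ else sum(lc$class == "dispersed")
  )
}

#' Chromosome-painting style composition plot
#'
#' Stacked bars of unit contributions per target chromosome, the standard
#' way to read fusions at a glance.
#'
#' @param object An `lsu_composition`.
#' @param min_markers Hide contributions below this many markers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsu_composition <- function(object, min_markers = 1, ...) {
  d <- tidy(object)
  d <- d[d$n_markers >= min_markers, ]
  d$target_sequence <- factor(d$target_sequence,
                              levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$n_markers, y = .data$target_sequence, fill = .data$lsu_id
  )) +
    ggplot2::geom_col(colour = "grey20", linewidth = 0.2) +
    ggplot2::labs(x = "assigned markers", y = NULL, fill = "unit") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
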