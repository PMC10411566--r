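#' Detect small nonreciprocal transpositions
#'
#' Scans each target chromosome in positional order for maximal runs of
#' consecutive markers that belong to a unit which is *not* a component of
#' that chromosome (components as called by [classify_composition()]).
#' Runs of at most `max_run` markers are transposition events; longer
#' foreign runs are flagged as translocated segments and reported
#' separately, never counted as transpositions. Every flagged marker
#' belongs to exactly one event.
#'
#' @param assignment An `lsu_assignment` from [assign_markers()].
#' @param composition A classified `lsu_composition`
#'   ([classify_composition()]).
#' @param max_run Largest run length still called a transposition
#'   (default 3, i.e. single markers or groups of 2-3).
#' @return A tibble with one row per event: `event_id`, `target_sequence`,
#'   `lsu_id`, `run_size`, `kind` (`"transposition"` or
#'   `"translocated_segment"`), `first_target_rank`, and a `marker_ids`
#'   list-column with the run's markers in target order.
#' @export
detect_transpositions <- function(assignment, composition, max_run = 3) {
  if (!inherits(assignment, "lsu_assignment")) {
    stop("`assignment` must come from assign_markers()", call. = FALSE)
  }
  if (!inherits(composition, "lsu_composition") ||
      is.null(composition$chromosome_calls)) {
    stop("`composition` must be classified; run classify_composition()",
         call. = FALSE)
  }
  if (max_run < 1) stop("`max_run` must be at least 1", call. = FALSE)

  comps <- strsplit(composition$chromosome_calls$components, "+", fixed = TRUE)
  names(comps) <- composition$chromosome_calls$target_sequence

  a <- assignment[!is.na(assignment$lsu_id), ]
  a <- a[order(a$target_sequence, a$target_rank), ]
  rows <- lapply(split(seq_len(nrow(a)), a$target_sequence), function(i) {
    s <- a$target_sequence[i[1]]
    l <- a$lsu_id[i]
    foreign <- !(l %in% (comps[[s]] %||% character()))
    g <- ifelse(foreign, l, ".__resident__")
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != ".__resident__"
    if (!any(keep)) return(NULL)
    purrr::map(which(keep), function(j) {
      run <- i[starts[j]:ends[j]]
      tibble::tibble(
        target_sequence = s,
        lsu_id = r$values[j],
        run_size = length(run),
        kind = if (length(run) <= max_run) "transposition" else "translocated_segment",
        first_target_rank = a$target_rank[run[1]],
        marker_ids = list(a$marker_id[run])
      )
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(unname(rows))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      target_sequence = character(), lsu_id = character(),
      run_size = integer(), kind = character(),
      first_target_rank = numeric(), marker_ids = list()
    )
  }
  out <- out[order(out$target_sequence, out$first_target_rank), ]
  dplyr::bind_cols(tibble::tibble(event_id = seq_len(nrow(out))), out)
}

# Breakpoints in one group of shared markers: take the markers in target
# order, re-rank their anchor ranks 1..m within the shared set, and count
# adjacent pairs whose rank difference is not +-1. Re-ranking makes the
# count robust to markers missing from the target.
.group_breakpoints <- function(anchor_ranks_in_target_order) {
  m <- length(anchor_ranks_in_target_order)
  if (m < 2) return(0L)
  r <- rank(anchor_ranks_in_target_order)
  sum(abs(diff(r)) != 1)
}

#' Count marker-order breakpoints within units
#'
#' For every (target chromosome x unit) group of shared markers, counts
#' adjacencies between consecutive markers (in target order) whose anchor
#' ranks are not consecutive, after re-ranking the anchor ranks 1..m within
#' the group's shared marker set. Inversions leave 2 such breakpoints and
#' translocations 3 as footprints in the rearranged chromosome. Chromosome
#' ends and junctions between different units on a fused chromosome are not
#' breakpoints, and counting is unsigned: a whole-group reversal leaves 0.
#' Markers belonging to transposition events are removed first so each
#' transposition is counted once as an event, not three times as
#' breakpoints.
#'
#' @param assignment An `lsu_assignment`.
#' @param transpositions Event tibble from [detect_transpositions()]
#'   (optional; `NULL` counts on all assigned markers).
#' @param lengths Optional sequence-length tibble for the target genome,
#'   used to express totals as per-Mbp rates over the marker-bearing
#'   sequences. Pass [infer_sequence_lengths()] output when no FASTA index
#'   is available; the rates are then flagged as inferred.
#' @return An object of class `lsu_breakpoints`: list with `groups` (tibble
#'   `target_sequence`, `lsu_id`, `n_shared`, `n_breakpoints`), `totals`
#'   (breakpoints within units, single and grouped transpositions,
#'   translocated segments), and when `lengths` is given `rates`
#'   (`breakpoints_per_mbp`, `transpositions_per_mbp`), `denominator_mbp`
#'   and `lengths_inferred`.
#' @export
count_breakpoints <- function(assignment, transpositions = NULL, lengths = NULL) {
  if (!inherits(assignment, "lsu_assignment")) {
    stop("`assignment` must come from assign_markers()", call. = FALSE)
  }
  a <- assignment[!is.na(assignment$lsu_id), ]
  n_single <- 0L
  n_grouped <- 0L
  n_segments <- 0L
  max_run <- 3
  if (!is.null(transpositions) && nrow(transpositions) > 0) {
    ev <- transpositions[transpositions$kind == "transposition", ]
    n_single <- sum(ev$run_size == 1)
    n_grouped <- sum(ev$run_size >= 2)
    n_segments <- sum(transpositions$kind == "translocated_segment")
    drop_ids <- unlist(ev$marker_ids)
    a <- a[!a$marker_id %in% drop_ids, ]
  }
  a <- a[order(a$target_sequence, a$target_rank), ]
  key <- paste(a$target_sequence, a$lsu_id, sep = "\r")
  groups <- split(a$anchor_rank, factor(key, levels = unique(key)))
  bp <- vapply(groups, .group_breakpoints, integer(1))
  ids <- strsplit(names(groups), "\r", fixed = TRUE)
  groups_tbl <- tibble::tibble(
    target_sequence = vapply(ids, `[[`, character(1), 1L),
    lsu_id = vapply(ids, `[[`, character(1), 2L),
    n_shared = vapply(groups, length, integer(1)),
    n_breakpoints = as.integer(bp)
  )
  out <- list(
    groups = groups_tbl,
    totals = list(
      breakpoints_within_lsus = sum(groups_tbl$n_breakpoints),
      transpositions_single = as.integer(n_single),
      transpositions_grouped = as.integer(n_grouped),
      translocated_segments = as.integer(n_segments)
    ),
    target_name = attr(assignment, "target_name"),
    anchor_name = attr(assignment, "anchor_name")
  )
  if (!is.null(lengths)) {
    seqs <- unique(assignment$target_sequence)
    denom <- per_mbp(1, lengths, sequences = seqs)
    out$denominator_mbp <- 1 / as.numeric(denom)
    out$lengths_inferred <- attr(denom, "provenance") == "inferred"
    out$rates <- list(
      breakpoints_per_mbp = out$totals$breakpoints_within_lsus / out$denominator_mbp,
      transpositions_per_mbp = (n_single + n_grouped) / out$denominator_mbp
    )
  }
  class(out) <- "lsu_breakpoints"
  out
}

#' Brute-force breakpoint oracle on a rank permutation
#'
#' Independent reference implementation used for cross-checking: given the
#' anchor ranks of one group's markers in target order (a permutation of
#' 1..m), enumerates the adjacent pairs whose absolute rank difference is
#' not 1.
#'
#' @param ranks An integer permutation of `1:length(ranks)`.
#' @return The breakpoint count, an integer.
#' @export
#' @examples
#' breakpoints_oracle(c(1, 2, 6, 5, 4, 3, 7, 8)) # one internal inversion -> 2
breakpoints_oracle <- function(ranks) {
  m <- length(ranks)
  if (m < 1 || !setequal(ranks, seq_len(m)) || anyDuplicated(ranks)) {
    stop("`ranks` must be a permutation of 1..m", call. = FALSE)
  }
  n <- 0L
  for (i in seq_len(m - 1)) {
    if (abs(ranks[i + 1] - ranks[i]) != 1) n <- n + 1L
  }
  n
}

#' Express an event count as a per-Mbp rate
#'
#' @param count Non-negative event count.
#' @param lengths Sequence-length tibble ([load_sequence_lengths()] or
#'   [infer_sequence_lengths()]).
#' @param sequences Optional character vector restricting the denominator
#'   to these sequences (e.g. the marker-bearing ones); default uses all
#'   sequences in `lengths`.
#' @return The rate (count per Mbp) with attribute `provenance` set to
#'   `"supplied"` or `"inferred"` according to where the lengths came from.
#' @export
per_mbp <- function(count, lengths, sequences = NULL) {
  if (count < 0) stop("`count` must be non-negative", call. = FALSE)
  len <- lengths
  if (!is.null(sequences)) {
    len <- len[len$sequence_id %in% sequences, ]
  }
  denom <- sum(len$length) / 1e6
  if (!length(denom) || denom <= 0) {
    stop("zero-length denominator: no matching sequences in `lengths`",
         call. = FALSE)
  }
  structure(count / denom,
            provenance = if (isTRUE(attr(lengths, "inferred"))) "inferred" else "supplied")
}

#' @export
print.lsu_breakpoints <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Rearrangement report (%s vs %s units)\n",
              x$target_name %||% "target", x$anchor_name %||% "anchor"))
  cat(sprintf("  breakpoints within units: %d\n", t$breakpoints_within_lsus))
  cat(sprintf("  transpositions: %d single, %d groups of 2-3 (%d larger segments)\n",
              t$transpositions_single, t$transpositions_grouped,
              t$translocated_segments))
  if (!is.null(x$rates)) {
    cat(sprintf("  rates over %.1f Mbp (%s lengths): %.2f breakpoints/Mbp, %.2f transpositions/Mbp\n",
                x$denominator_mbp,
                if (isTRUE(x$lengths_inferred)) "inferred" else "supplied",
                x$rates$breakpoints_per_mbp, x$rates$transpositions_per_mbp))
  }
  invisible(x)
}

#' @export
tidy.lsu_breakpoints <- function(x, ...) x$groups

#' One-row rearrangement summary per genome
#'
#' Mirrors the standard per-genome report: breakpoints within units,
#' single-marker and 2-3 marker transpositions, and the corresponding
#' per-Mbp rates when lengths were available.
#'
#' @param x An `lsu_breakpoints` object.
#' @param ... Unused.
#' @export
glance.lsu_breakpoints <- function(x, ...) {
  tibble::tibble(
    target = x$target_name %||% NA_character_,
    breakpoints_within_lsus = x$totals$breakpoints_within_lsus,
    breakpoints_per_mbp = if (is.null(x$rates)) NA_real_ else x$rates$breakpoints_per_mbp,
    transpositions_single = x$totals$transpositions_single,
    transpositions_grouped = x$totals$transpositions_grouped,
    transpositions_per_mbp = if (is.null(x$rates)) NA_real_ else x$rates$transpositions_per_mbp,
    translocated_segments = x$totals$translocated_segments,
    denominator_mbp = x$denominator_mbp %||% NA_real_,
    lengths_inferred = x$lengths_inferred %||% NA
  )
}

#' Breakpoints per chromosome plot
#'
#' @param object An `lsu_breakpoints` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsu_breakpoints <- function(object, ...) {
  d <- object$groups |>
    dplyr::group_by(.data$target_sequence) |>
    dplyr::summarise(n_breakpoints = sum(.data$n_breakpoints), .groups = "drop")
  d$target_sequence <- factor(d$target_sequence, levels = rev(d$target_sequence))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_breakpoints,
                                  y = .data$target_sequence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "order breakpoints within units", y = NULL) +
    ggplot2::theme_minimal()
}
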