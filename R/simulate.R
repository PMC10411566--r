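# Seeded karyotype-rearrangement simulator. A synthetic anchor genome is a
# set of chromosome-scale sequences carrying evenly spaced (jittered)
# single-copy markers; rearranged descendants are produced by applying an
# explicit, ordered list of events (fusions, fissions, inversions, small
# transpositions, marker losses and duplications). Both genomes are emitted
# as standard BUSCO full tables, and the event log doubles as ground truth:
# for non-interacting event sets the expected pipeline readout (breakpoints,
# transposition counts, fusion/split calls) is known analytically.

#' Generate a synthetic anchor genome marker table
#'
#' Markers named `SYNT00001at0000`, `SYNT00002at0000`, ... are laid out in
#' order along each chromosome, evenly spaced with seeded jitter, all with
#' status `Complete`. With the defaults the anchor mimics the scale of a
#' 31-chromosome lepidopteran genome (~170 markers per ~20 Mbp
#' chromosome); chromosome names are `Chr1` ... `Chr{n-1}` plus `ChrZ`, so
#' the default unit naming places the Z unit last.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param markers_per_chromosome Markers per chromosome; scalar or one
#'   value per chromosome.
#' @param chromosome_length Chromosome length in bp; scalar or per
#'   chromosome.
#' @param jitter Spacing noise in `[0, 1)`: each marker is displaced by up
#'   to `0.45 * jitter` of the inter-marker spacing, which keeps
#'   coordinates strictly increasing.
#' @param seed Integer seed; the same seed gives a byte-identical table.
#' @return A marker-record tibble (see [parse_full_table()]) with the true
#'   chromosome lengths attached as `attr(, "sim_lengths")`.
#' @export
make_anchor <- function(n_chromosomes = 31, markers_per_chromosome = 170,
                        chromosome_length = 2e7, jitter = 0.2, seed = 1) {
  stopifnot(n_chromosomes >= 1, all(markers_per_chromosome >= 1),
            jitter >= 0, jitter < 1)
  m <- rep_len(markers_per_chromosome, n_chromosomes)
  L <- rep_len(chromosome_length, n_chromosomes)
  if (any(L <= m)) stop("chromosome_length must exceed the marker count", call. = FALSE)
  chrom_names <- if (n_chromosomes >= 2) {
    c(paste0("Chr", seq_len(n_chromosomes - 1)), "ChrZ")
  } else {
    "Chr1"
  }
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_chromosomes), function(i) {
      s <- L[i] / (m[i] + 1)
      start <- round(seq_len(m[i]) * s + jitter * s * runif(m[i], -0.45, 0.45))
      gene <- max(200, round(0.25 * s))
      tibble::tibble(
        sequence_id = chrom_names[i],
        start = start,
        end = pmin(start + gene - 1, L[i]),
        strand = sample(c("+", "-"), m[i], replace = TRUE),
        score = round(runif(m[i], 200, 1500), 1)
      )
    }) |> purrr::list_rbind()
    out <- tibble::tibble(
      marker_id = sprintf("SYNT%05dat0000", seq_len(nrow(rows))),
      status = "Complete",
      sequence_id = rows$sequence_id,
      start = rows$start,
      end = rows$end,
      strand = rows$strand,
      score = rows$score,
      length = rows$end - rows$start + 1
    )
    attr(out, "sim_lengths") <- tibble::tibble(sequence_id = chrom_names,
                                               length = L)
    out
  })
}

# ---- event constructors ----------------------------------------------------

.ev <- function(type, ...) structure(list(type = type, ...), class = "lsu_event")

#' Rearrangement event constructors
#'
#' Build the ordered event list consumed by [apply_events()]. Indices refer
#' to marker positions (1-based, in current marker order) on the chromosome
#' *at the time the event is applied*; events are applied in list order
#' with no hidden reordering, so logs replay exactly.
#'
#' @param chrom_a,chrom_b,chrom,from_chrom,to_chrom Chromosome names.
#' @param name Optional name for a fusion product (default
#'   `"chromA--chromB"`).
#' @param after_marker Fission point: the new chromosomes carry markers
#'   `1..after_marker` and the rest.
#' @param from,to Inclusive marker-index range to invert.
#' @param run_start,run_size The moved run: `run_size` adjacent markers
#'   starting at `run_start` on `from_chrom`.
#' @param insert_after Insertion point on `to_chrom` (0 = before the first
#'   marker).
#' @param marker_ids Explicit markers to lose or duplicate.
#' @param fraction Alternative to `marker_ids`: lose/duplicate every k-th
#'   marker so that about this fraction is affected (systematic, hence
#'   deterministic; use [random_events()] for randomized picks).
#' @return An object of class `lsu_event`.
#' @name events
NULL

#' @rdname events
#' @export
ev_fusion <- function(chrom_a, chrom_b, name = NULL) {
  .ev("fusion", chrom_a = chrom_a, chrom_b = chrom_b,
      name = name %||% paste(chrom_a, chrom_b, sep = "--"))
}

#' @rdname events
#' @export
ev_fission <- function(chrom, after_marker) {
  .ev("fission", chrom = chrom, after_marker = as.integer(after_marker))
}

#' @rdname events
#' @export
ev_inversion <- function(chrom, from, to) {
  .ev("inversion", chrom = chrom, from = as.integer(from), to = as.integer(to))
}

#' @rdname events
#' @export
ev_transposition <- function(from_chrom, run_start, run_size, to_chrom,
                             insert_after) {
  .ev("transposition", from_chrom = from_chrom,
      run_start = as.integer(run_start), run_size = as.integer(run_size),
      to_chrom = to_chrom, insert_after = as.integer(insert_after))
}

#' @rdname events
#' @export
ev_loss <- function(marker_ids = NULL, fraction = NULL) {
  .ev("loss", marker_ids = marker_ids, fraction = fraction)
}

#' @rdname events
#' @export
ev_duplication <- function(marker_ids = NULL, fraction = NULL) {
  .ev("duplication", marker_ids = marker_ids, fraction = fraction)
}

# ---- state -----------------------------------------------------------------

.sim_state <- function(anchor) {
  .check_records(anchor)
  pos <- anchor[!is.na(anchor$sequence_id) & !is.na(anchor$start) &
                  anchor$status != "Missing", ]
  pos <- pos[order(match(pos$sequence_id, unique(pos$sequence_id)), pos$start), ]
  lens <- attr(anchor, "sim_lengths")
  if (is.null(lens)) lens <- infer_sequence_lengths(anchor)
  chroms <- split(pos$marker_id, factor(pos$sequence_id,
                                        levels = unique(pos$sequence_id)))
  coords <- lapply(split(pos[, c("start", "end")],
                         factor(pos$sequence_id, levels = unique(pos$sequence_id))),
                   as.list)
  list(
    chroms = chroms,
    coords = coords,
    lens = stats::setNames(lens$length, lens$sequence_id),
    strand = stats::setNames(pos$strand, pos$marker_id),
    score = stats::setNames(pos$score, pos$marker_id),
    lost = anchor$marker_id[anchor$status == "Missing"],
    dup = unique(anchor$marker_id[anchor$status == "Duplicated"])
  )
}

.systematic_pick <- function(all_ids, fraction) {
  k <- max(1L, round(1 / fraction))
  all_ids[seq(1L, length(all_ids), by = k)]
}

.find_chrom <- function(state, id) {
  for (ch in names(state$chroms)) {
    if (id %in% state$chroms[[ch]]) return(ch)
  }
  NA_character_
}

#' Apply rearrangement events to an anchor genome
#'
#' Applies the events in list order, recomputes marker coordinates so that
#' each chromosome's markers stay strictly ordered (untouched chromosomes
#' keep their original coordinates), and emits the descendant genome as a
#' marker-record tibble together with a ground-truth log. Lost markers
#' reappear as `Missing` rows; duplicated markers yield two `Duplicated`
#' lines each. Inverted markers have their strands flipped (recorded,
#' though order-breakpoint counting is unsigned).
#'
#' When the event set is non-interacting -- fusion and fission chromosomes
#' untouched by anything else, inversion ranges internal and separated by
#' at least one marker, one transposition per donor/recipient pair with
#' recipient otherwise untouched, losses and duplications confined to
#' otherwise untouched chromosomes -- the truth log carries an analytic
#' `expected_signature`: each internal inversion leaves 2 order
#' breakpoints, each moved run one transposition event of its size, each
#' fusion a `fusion_of_k` chromosome and each fission a split unit.
#' Interacting event lists are applied all the same, but no analytic
#' signature is claimed (`expected_signature = NULL`). The signature maps
#' anchor chromosomes to unit names with the default
#' `"by_sequence_suffix"` policy.
#'
#' @param anchor Anchor marker records, e.g. from [make_anchor()].
#' @param events A list of [events] (or [random_events()] output).
#' @param max_run Run-size limit used to classify expected transpositions
#'   in the signature (matching [detect_transpositions()]).
#' @return A list with `target` (marker-record tibble, true sequence
#'   lengths in `attr(, "sim_lengths")`) and `truth` (class
#'   `simulation_truth`: resolved `events`, `expected_signature`,
#'   `non_overlapping`, `lengths`).
#' @export
apply_events <- function(anchor, events, max_run = 3) {
  state <- .sim_state(anchor)
  state0 <- state
  resolved <- vector("list", length(events))

  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (!inherits(ev, "lsu_event")) {
      stop("event ", i, " is not an lsu_event", call. = FALSE)
    }
    fail <- function(msg) {
      stop("event ", i, " (", ev$type, "): ", msg, call. = FALSE)
    }
    need_chrom <- function(ch) {
      if (!ch %in% names(state$chroms)) fail(paste0("no chromosome \"", ch, "\""))
    }
    res <- switch(ev$type,
      fusion = {
        need_chrom(ev$chrom_a); need_chrom(ev$chrom_b)
        if (ev$chrom_a == ev$chrom_b) fail("cannot fuse a chromosome with itself")
        if (ev$name %in% names(state$chroms)) fail("product name already in use")
        a <- state$chroms[[ev$chrom_a]]; b <- state$chroms[[ev$chrom_b]]
        state$chroms[[ev$name]] <- c(a, b)
        state$lens[ev$name] <- state$lens[ev$chrom_a] + state$lens[ev$chrom_b]
        state$chroms[[ev$chrom_a]] <- NULL
        state$chroms[[ev$chrom_b]] <- NULL
        list(type = "fusion", inputs = c(ev$chrom_a, ev$chrom_b),
             product = ev$name, n_markers = c(length(a), length(b)))
      },
      fission = {
        need_chrom(ev$chrom)
        ids <- state$chroms[[ev$chrom]]
        m <- length(ids)
        if (ev$after_marker < 1 || ev$after_marker >= m) {
          fail(sprintf("after_marker %d out of range 1..%d", ev$after_marker, m - 1))
        }
        p <- paste0(ev$chrom, c("_p1", "_p2"))
        state$chroms[[p[1]]] <- ids[seq_len(ev$after_marker)]
        state$chroms[[p[2]]] <- ids[(ev$after_marker + 1):m]
        L <- state$lens[ev$chrom]
        state$lens[p[1]] <- round(L * ev$after_marker / m)
        state$lens[p[2]] <- L - state$lens[p[1]]
        state$chroms[[ev$chrom]] <- NULL
        list(type = "fission", input = ev$chrom, products = p,
             after_marker = ev$after_marker, n_markers = m)
      },
      inversion = {
        need_chrom(ev$chrom)
        ids <- state$chroms[[ev$chrom]]
        m <- length(ids)
        if (ev$from < 1 || ev$to > m || ev$from >= ev$to) {
          fail(sprintf("range %d..%d invalid on %d markers", ev$from, ev$to, m))
        }
        seg <- ids[ev$from:ev$to]
        state$chroms[[ev$chrom]][ev$from:ev$to] <- rev(seg)
        state$strand[seg] <- ifelse(state$strand[seg] == "+", "-",
                                    ifelse(state$strand[seg] == "-", "+", "unknown"))
        list(type = "inversion", chrom = ev$chrom, from = ev$from, to = ev$to,
             internal = c(ev$from > 1, ev$to < m), marker_ids = seg)
      },
      transposition = {
        need_chrom(ev$from_chrom); need_chrom(ev$to_chrom)
        if (ev$from_chrom == ev$to_chrom) fail("donor and recipient must differ")
        src <- state$chroms[[ev$from_chrom]]
        run_end <- ev$run_start + ev$run_size - 1L
        if (ev$run_size < 1 || ev$run_start < 1 || run_end > length(src)) {
          fail(sprintf("run %d..%d invalid on %d markers", ev$run_start,
                       run_end, length(src)))
        }
        run <- src[ev$run_start:run_end]
        dst <- state$chroms[[ev$to_chrom]]
        if (ev$insert_after < 0 || ev$insert_after > length(dst)) {
          fail(sprintf("insert_after %d invalid on %d markers",
                       ev$insert_after, length(dst)))
        }
        state$chroms[[ev$from_chrom]] <- src[-(ev$run_start:run_end)]
        state$chroms[[ev$to_chrom]] <- append(dst, run, after = ev$insert_after)
        list(type = "transposition", from_chrom = ev$from_chrom,
             to_chrom = ev$to_chrom, run_size = ev$run_size,
             insert_after = ev$insert_after, marker_ids = run)
      },
      loss = {
        ids <- ev$marker_ids
        if (is.null(ids)) {
          if (is.null(ev$fraction)) fail("needs marker_ids or fraction")
          ids <- .systematic_pick(unlist(state$chroms, use.names = FALSE),
                                  ev$fraction)
        }
        miss <- ids[!ids %in% unlist(state$chroms, use.names = FALSE)]
        if (length(miss)) fail(paste0("marker(s) not present: ",
                                      paste(head(miss, 3), collapse = ", ")))
        state$chroms <- lapply(state$chroms, function(v) v[!v %in% ids])
        state$lost <- c(state$lost, ids)
        list(type = "loss", marker_ids = ids)
      },
      duplication = {
        ids <- ev$marker_ids
        if (is.null(ids)) {
          if (is.null(ev$fraction)) fail("needs marker_ids or fraction")
          ids <- .systematic_pick(unlist(state$chroms, use.names = FALSE),
                                  ev$fraction)
        }
        for (id in ids) {
          ch <- .find_chrom(state, id)
          if (is.na(ch)) fail(paste0("marker not present: ", id))
          state$chroms[[ch]] <- c(state$chroms[[ch]], id)
        }
        state$dup <- unique(c(state$dup, ids))
        list(type = "duplication", marker_ids = ids)
      },
      fail("unknown event type")
    )
    resolved[[i]] <- res
  }

  check <- .check_events_independent(state0, resolved)
  sig <- if (check$ok) {
    .expected_signature(state0, resolved, max_run = max_run)
  } else {
    NULL
  }

  target <- .emit_records(state, state0)
  truth <- structure(
    list(events = resolved, expected_signature = sig,
         non_overlapping = check$ok,
         lengths = tibble::tibble(sequence_id = names(state$chroms),
                                  length = unname(state$lens[names(state$chroms)]))),
    class = "simulation_truth"
  )
  list(target = target, truth = truth)
}

# Emit the BUSCO-style table for the current state. Chromosomes whose
# marker content is unchanged keep the anchor's coordinates; edited ones
# are re-spaced evenly along their (possibly new) length.
.emit_records <- function(state, state0) {
  rows <- purrr::map(names(state$chroms), function(ch) {
    ids <- state$chroms[[ch]]
    if (length(ids) == 0) return(NULL)
    L <- unname(state$lens[ch])
    untouched <- ch %in% names(state0$chroms) &&
      identical(ids, state0$chroms[[ch]])
    if (untouched) {
      co <- state0$coords[[ch]]
      start <- co$start; end <- co$end
    } else {
      s <- L / (length(ids) + 1)
      start <- round(seq_along(ids) * s)
      gene <- max(200, round(0.25 * s))
      end <- pmin(start + gene - 1, L)
    }
    tibble::tibble(
      marker_id = ids, sequence_id = ch, start = start, end = end,
      strand = unname(state$strand[ids]), score = unname(state$score[ids])
    )
  }) |> purrr::list_rbind()
  dup <- unique(state$dup)
  placed <- tibble::tibble(
    marker_id = rows$marker_id,
    status = ifelse(rows$marker_id %in% dup, "Duplicated", "Complete"),
    sequence_id = rows$sequence_id,
    start = rows$start, end = rows$end, strand = rows$strand,
    score = rows$score, length = rows$end - rows$start + 1
  )
  lost <- setdiff(unique(state$lost), placed$marker_id)
  if (length(lost)) {
    placed <- dplyr::bind_rows(placed, tibble::tibble(
      marker_id = lost, status = "Missing", sequence_id = NA_character_,
      start = NA_real_, end = NA_real_, strand = "unknown",
      score = NA_real_, length = NA_real_
    ))
  }
  placed <- placed[order(placed$marker_id, placed$start), ]
  attr(placed, "sim_lengths") <- tibble::tibble(
    sequence_id = names(state$chroms),
    length = unname(state$lens[names(state$chroms)])
  )
  placed
}

# Conservative non-interaction check on the resolved event log: every rule
# guarantees that the analytic signature is exact. Interacting lists are
# legal input to apply_events, they just carry no signature.
.check_events_independent <- function(state0, resolved) {
  m0 <- vapply(state0$chroms, length, integer(1))
  structural <- character() # chroms under fusion/fission
  ranges <- list()          # per chrom: matrix of (from, to) for inversions + donor runs
  recipients <- character()
  donors <- character()
  touched_markers <- character()
  add_range <- function(ch, from, to) {
    ranges[[ch]] <<- rbind(ranges[[ch]], c(from, to))
  }
  for (res in resolved) {
    switch(res$type,
      fusion = structural <- c(structural, res$inputs, res$product),
      fission = structural <- c(structural, res$input, res$products),
      inversion = add_range(res$chrom, res$from, res$to),
      transposition = {
        donors <- c(donors, res$from_chrom)
        recipients <- c(recipients, res$to_chrom)
        i <- match(res$marker_ids[1], state0$chroms[[res$from_chrom]])
        if (is.na(i)) return(list(ok = FALSE))
        add_range(res$from_chrom, i, i + res$run_size - 1L)
        touched_markers <- c(touched_markers, res$marker_ids)
      },
      loss = touched_markers <- c(touched_markers, res$marker_ids),
      duplication = touched_markers <- c(touched_markers, res$marker_ids)
    )
  }
  if (anyDuplicated(structural)) return(list(ok = FALSE))
  if (anyDuplicated(donors) || anyDuplicated(recipients)) return(list(ok = FALSE))
  busy <- c(structural, donors, names(ranges))
  if (any(recipients %in% busy)) return(list(ok = FALSE))
  if (any(names(ranges) %in% structural)) return(list(ok = FALSE))
  for (ch in names(ranges)) {
    r <- ranges[[ch]][order(ranges[[ch]][, 1]), , drop = FALSE]
    if (r[1, 1] < 2 || r[nrow(r), 2] > m0[ch] - 1) return(list(ok = FALSE))
    if (nrow(r) > 1 && any(r[-1, 1] < r[-nrow(r), 2] + 2)) return(list(ok = FALSE))
  }
  # losses/duplications only on chromosomes free of structural edits
  lost_dup <- setdiff(touched_markers,
                      unlist(lapply(resolved, function(r)
                        if (r$type == "transposition") r$marker_ids else NULL)))
  if (length(lost_dup)) {
    ch_of <- vapply(lost_dup, function(id) {
      hits <- names(state0$chroms)[vapply(state0$chroms, function(v) id %in% v, logical(1))]
      if (length(hits)) hits[1] else NA_character_
    }, character(1))
    if (anyNA(ch_of)) return(list(ok = FALSE))
    if (any(ch_of %in% c(structural, donors, recipients, names(ranges)))) {
      return(list(ok = FALSE))
    }
  }
  list(ok = TRUE)
}

.expected_signature <- function(state0, resolved, max_run = 3) {
  m0 <- vapply(state0$chroms, length, integer(1))
  ordered <- .order_sequences_suffix(names(state0$chroms))
  lsu_map <- stats::setNames(paste0("LSU_", seq_along(ordered)), ordered)

  inv <- purrr::keep(resolved, ~ .x$type == "inversion")
  bp <- sum(vapply(inv, function(r) {
    (r$from > 1) + (r$to < m0[r$chrom])
  }, numeric(1)))
  tr <- purrr::keep(resolved, ~ .x$type == "transposition")
  sizes <- vapply(tr, `[[`, integer(1), "run_size")
  fus <- purrr::keep(resolved, ~ .x$type == "fusion")
  fis <- purrr::keep(resolved, ~ .x$type == "fission")

  final_chroms <- names(state0$chroms)
  cls <- stats::setNames(rep("single", length(final_chroms)), final_chroms)
  for (r in fus) {
    cls <- cls[setdiff(names(cls), r$inputs)]
    cls[r$product] <- "fusion_of_2"
  }
  for (r in fis) {
    cls <- cls[setdiff(names(cls), r$input)]
    cls[r$products] <- "single"
  }
  list(
    breakpoints_total = as.integer(bp),
    transpositions_single = sum(sizes == 1),
    transpositions_grouped = sum(sizes >= 2 & sizes <= max_run),
    translocated_segments = sum(sizes > max_run),
    fusions = purrr::map(fus, function(r) {
      list(product = r$product,
           units = unname(lsu_map[r$inputs]), k = length(r$inputs))
    }),
    split_units = vapply(fis, function(r) unname(lsu_map[r$input]), character(1)),
    chromosome_classes = tibble::tibble(target_sequence = names(cls),
                                        class = unname(cls)),
    lsu_map = lsu_map
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  types <- vapply(x$events, `[[`, character(1), "type")
  cat(sprintf("Simulation truth: %d events (%s)\n", length(types),
              paste(names(table(types)), table(types), sep = "=", collapse = ", ")))
  if (!is.null(x$expected_signature)) {
    s <- x$expected_signature
    cat(sprintf("  non-interacting; expect %d breakpoints, %d single + %d grouped transpositions\n",
                s$breakpoints_total, s$transpositions_single,
                s$transpositions_grouped))
  } else {
    cat("  interacting events: no analytic signature\n")
  }
  invisible(x)
}

#' Draw a random, non-interacting event list
#'
#' Samples a valid event list in which no two events touch each other's
#' chromosomes or marker ranges, so that [apply_events()] can attach an
#' exact analytic signature. Fusion and fission chromosomes are used by no
#' other event; inversions get internal, mutually separated index ranges;
#' each transposition uses its own donor and recipient chromosome; losses
#' and duplications hit interior markers of otherwise untouched
#' chromosomes. Deterministic given `seed`.
#'
#' @param anchor Anchor marker records ([make_anchor()]).
#' @param n_fusions,n_fissions,n_inversions,n_transpositions Event counts.
#' @param n_losses,n_duplications Numbers of markers to lose / duplicate.
#' @param run_sizes Transposition run sizes to sample from (default 1-3).
#' @param min_fission_side Minimum markers on each fission product.
#' @param seed Integer seed.
#' @return A list of [events] (class `lsu_events`).
#' @export
random_events <- function(anchor, n_fusions = 0, n_fissions = 0,
                          n_inversions = 0, n_transpositions = 0,
                          n_losses = 0, n_duplications = 0,
                          run_sizes = 1:3, min_fission_side = 10, seed = 1) {
  state <- .sim_state(anchor)
  chroms <- names(state$chroms)
  m <- vapply(state$chroms, length, integer(1))
  n_inv_chroms <- min(n_inversions, max(0L, length(chroms) - 2 * n_fusions -
                                          n_fissions - 2 * n_transpositions -
                                          (n_losses + n_duplications > 0)))
  need <- 2 * n_fusions + n_fissions + (n_inversions > 0) * max(1, n_inv_chroms) +
    2 * n_transpositions + (n_losses + n_duplications > 0)
  if (need > length(chroms)) {
    stop("event rates cannot be satisfied with ", length(chroms),
         " chromosomes", call. = FALSE)
  }
  withr::with_seed(seed, {
    pick <- function(v) v[sample.int(length(v), 1)] # no 1:x surprise
    pool <- sample(chroms)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    events <- list()
    if (n_fusions > 0) {
      for (i in seq_len(n_fusions)) {
        pair <- take(2)
        events <- c(events, list(ev_fusion(pair[1], pair[2])))
      }
    }
    if (n_fissions > 0) {
      for (ch in take(n_fissions)) {
        lo <- min_fission_side
        hi <- m[ch] - min_fission_side
        if (lo > hi) stop("chromosome ", ch, " too small to fission", call. = FALSE)
        events <- c(events, list(ev_fission(ch, pick(lo:hi))))
      }
    }
    if (n_inversions > 0) {
      inv_chroms <- take(max(1, n_inv_chroms))
      host <- rep_len(inv_chroms, n_inversions)
      for (ch in unique(host)) {
        k <- sum(host == ch)
        interior <- (m[ch] - 2)
        block <- interior %/% k
        if (block < 6) stop("too many inversions for chromosome ", ch, call. = FALSE)
        for (b in seq_len(k)) {
          lo <- 2L + (b - 1L) * block
          hi <- lo + block - 3L # leave a >= 2 gap to the next block
          from <- pick(lo:(hi - 1))
          to <- pick((from + 1):hi)
          events <- c(events, list(ev_inversion(ch, from, to)))
        }
      }
    }
    if (n_transpositions > 0) {
      for (i in seq_len(n_transpositions)) {
        src <- take(1)
        dst <- take(1)
        size <- pick(run_sizes)
        if (m[src] - size < 2 || m[dst] < 2) {
          stop("chromosome too small for a transposition run", call. = FALSE)
        }
        start <- pick(2:(m[src] - size))
        at <- pick(1:(m[dst] - 1))
        events <- c(events, list(ev_transposition(src, start, size, dst, at)))
      }
    }
    if (n_losses + n_duplications > 0) {
      quiet_pool <- pool
      if (!length(quiet_pool)) stop("no untouched chromosome left for losses",
                                    call. = FALSE)
      pick_markers <- function(n, used) {
        out <- character(0)
        while (length(out) < n) {
          ch <- pick(quiet_pool)
          id <- state$chroms[[ch]][pick(3:(m[ch] - 2))]
          if (!id %in% c(out, used)) out <- c(out, id)
        }
        out
      }
      lost <- if (n_losses > 0) pick_markers(n_losses, character(0)) else character(0)
      if (n_losses > 0) events <- c(events, list(ev_loss(lost)))
      if (n_duplications > 0) {
        events <- c(events, list(ev_duplication(pick_markers(n_duplications, lost))))
      }
    }
    structure(events, class = "lsu_events", seed = seed)
  })
}

#' Markers strictly inside collinear segments
#'
#' Given an anchor and an event list, returns markers whose removal
#' provably cannot change any order-breakpoint count: markers at least two
#' index positions away from every event boundary, away from chromosome
#' ends, and outside fused/fissioned chromosomes and moved runs. Used to
#' exercise the re-ranking robustness of the breakpoint counter under
#' marker loss.
#'
#' @param anchor Anchor marker records.
#' @param events Event list the anchor will be subjected to.
#' @return Character vector of marker ids.
#' @export
collinear_interior_markers <- function(anchor, events) {
  state <- .sim_state(anchor)
  m <- vapply(state$chroms, length, integer(1))
  excluded_chroms <- character(0)
  windows <- stats::setNames(vector("list", length(m)), names(m))
  add_window <- function(ch, lo, hi) {
    lo <- max(1, lo)
    hi <- min(m[ch], hi)
    if (lo <= hi) windows[[ch]] <<- c(windows[[ch]], seq(lo, hi))
  }
  moved <- character(0)
  for (ev in events) {
    switch(ev$type,
      fusion = excluded_chroms <- c(excluded_chroms, ev$chrom_a, ev$chrom_b),
      fission = excluded_chroms <- c(excluded_chroms, ev$chrom),
      inversion = {
        add_window(ev$chrom, ev$from - 1, ev$from + 1)
        add_window(ev$chrom, ev$to - 1, ev$to + 1)
      },
      transposition = {
        add_window(ev$from_chrom, ev$run_start - 1,
                   ev$run_start + ev$run_size)
        add_window(ev$to_chrom, ev$insert_after, ev$insert_after + 1)
      },
      loss = moved <- c(moved, ev$marker_ids),
      duplication = moved <- c(moved, ev$marker_ids)
    )
  }
  out <- purrr::map(setdiff(names(m), excluded_chroms), function(ch) {
    idx <- setdiff(2:(m[ch] - 1), windows[[ch]])
    state$chroms[[ch]][idx]
  })
  setdiff(unlist(out), moved)
}
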