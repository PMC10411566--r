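# File-level orchestration of the four pipeline stages (define / assign /
# breakpoints / simulate). Every output is a flat TSV (or YAML/JSON for
# configuration and truth logs) with "#"-prefixed header lines echoing the
# package version and the configuration, so re-running a command with the
# same inputs reproduces byte-identical files.

.cfg_header <- function(config) {
  vals <- vapply(config, function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                                           collapse = ","), character(1))
  c(sprintf("# lsukit %s", as.character(packageVersion("lsukit"))),
    sprintf("# %s: %s", names(config), vals))
}

.write_tsv <- function(df, file, config = list()) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ",")
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], scientific = FALSE, trim = TRUE)
    df[[j]] <- ifelse(is.na(df[[j]]) | df[[j]] == "NA", "", as.character(df[[j]]))
  }
  lines <- c(.cfg_header(config),
             paste(names(df), collapse = "\t"),
             do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, file)
  invisible(file)
}

#' Read and write synteny unit tables
#'
#' The unit table is serialized as a TSV with columns `lsu_id`,
#' `marker_id`, `anchor_sequence`, `anchor_start`, `anchor_rank`, preceded
#' by `#` header lines recording the anchor name. [read_lsu_table()]
#' restores a full `lsu_table` object.
#'
#' @param x An `lsu_table`.
#' @param file Path.
#' @return `read_lsu_table()` returns an `lsu_table`;
#'   `write_lsu_table()` returns `file` invisibly.
#' @export
write_lsu_table <- function(x, file) {
  if (!inherits(x, "lsu_table")) stop("`x` must be an lsu_table", call. = FALSE)
  .write_tsv(as.data.frame(x), file,
             config = list(anchor_name = attr(x, "anchor_name")))
}

#' @rdname write_lsu_table
#' @export
read_lsu_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  anchor_name <- sub("^#\\s*anchor_name:\\s*", "",
                     grep("^#\\s*anchor_name:", comments, value = TRUE)[1])
  if (is.na(anchor_name)) anchor_name <- "anchor"
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  parts <- strsplit(body[-1], "\t", fixed = TRUE)
  df <- tibble::as_tibble(stats::setNames(
    lapply(seq_along(header), function(j) vapply(parts, `[[`, character(1), j)),
    header
  ))
  df$anchor_start <- as.numeric(df$anchor_start)
  df$anchor_rank <- as.numeric(df$anchor_rank)
  attr(df, "anchor_name") <- anchor_name
  attr(df, "lsu_names") <- unique(df$lsu_id)
  map <- df[!duplicated(df$lsu_id), ]
  attr(df, "lsu_map") <- stats::setNames(map$lsu_id, map$anchor_sequence)
  class(df) <- c("lsu_table", class(df))
  df
}

.as_records <- function(x) {
  if (is.character(x) && length(x) == 1) read_full_table(x) else x
}

.as_lengths <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) load_sequence_lengths(x) else x
}

#' Stage 1: define synteny units from an anchor full table
#'
#' Filters the anchor's BUSCO table, defines the units and writes
#' `units.tsv` and `coverage.tsv` into `out_dir`.
#'
#' @param anchor Path to the anchor `full_table.tsv`, or a marker-record
#'   tibble.
#' @param out_dir Output directory (created if needed).
#' @param lengths Optional path to a sequence-length table (or tibble).
#' @param naming_policy,drop_fragmented See [define_lsus()] and
#'   [filter_usable()].
#' @param anchor_name Label for the anchor genome.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `lsu_table`, `coverage` and the written
#'   file paths.
#' @export
lsu_define <- function(anchor, out_dir, lengths = NULL,
                       naming_policy = "by_sequence_suffix",
                       drop_fragmented = FALSE, anchor_name = "anchor",
                       quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- .as_records(anchor)
  lens <- .as_lengths(lengths)
  usable <- filter_usable(records, drop_fragmented = drop_fragmented,
                          quiet = quiet)
  tab <- define_lsus(usable, naming_policy = naming_policy, lengths = lens,
                     anchor_name = anchor_name)
  cov <- coverage_summary(usable, lengths = lens)
  cfg <- list(anchor_name = anchor_name, naming_policy = naming_policy,
              drop_fragmented = drop_fragmented)
  units_file <- file.path(out_dir, "units.tsv")
  write_lsu_table(tab, units_file)
  cov_file <- file.path(out_dir, "coverage.tsv")
  .write_tsv(cov, cov_file, config = cfg)
  invisible(list(lsu_table = tab, coverage = cov,
                 files = c(units = units_file, coverage = cov_file)))
}

#' Stage 2: assign a target genome to units and classify its composition
#'
#' Writes `assignment.tsv`, `hit_counts.tsv` (target sequences x units
#' matrix), `chromosome_calls.tsv` and `lsu_calls.tsv`.
#'
#' @param units Path to a `units.tsv` (or an `lsu_table`).
#' @param target Path to the target `full_table.tsv` (or records tibble).
#' @param out_dir Output directory.
#' @param min_component_markers,min_component_fraction,intact_fraction
#'   Classification thresholds, see [classify_composition()].
#' @param drop_fragmented,target_name,quiet As in [lsu_define()].
#' @return Invisibly, a list with `assignment`, `composition` and file
#'   paths.
#' @export
lsu_assign <- function(units, target, out_dir,
                       min_component_markers = 5,
                       min_component_fraction = 0.05,
                       intact_fraction = 0.95,
                       drop_fragmented = FALSE, target_name = "target",
                       quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (inherits(units, "lsu_table")) units else read_lsu_table(units)
  records <- .as_records(target)
  usable <- filter_usable(records, drop_fragmented = drop_fragmented,
                          quiet = quiet)
  asg <- assign_markers(usable, tab, target_name = target_name, quiet = quiet)
  comp <- classify_composition(
    composition_matrix(asg),
    min_component_markers = min_component_markers,
    min_component_fraction = min_component_fraction,
    intact_fraction = intact_fraction
  )
  cfg <- list(target_name = target_name,
              min_component_markers = min_component_markers,
              min_component_fraction = min_component_fraction,
              intact_fraction = intact_fraction)
  files <- c(
    assignment = file.path(out_dir, "assignment.tsv"),
    hit_counts = file.path(out_dir, "hit_counts.tsv"),
    chromosome_calls = file.path(out_dir, "chromosome_calls.tsv"),
    lsu_calls = file.path(out_dir, "lsu_calls.tsv")
  )
  .write_tsv(as.data.frame(asg), files["assignment"], cfg)
  mat <- tibble::as_tibble(as.data.frame(comp$matrix))
  mat <- dplyr::bind_cols(tibble::tibble(target_sequence = rownames(comp$matrix)), mat)
  .write_tsv(mat, files["hit_counts"], cfg)
  .write_tsv(comp$chromosome_calls, files["chromosome_calls"], cfg)
  .write_tsv(comp$lsu_calls, files["lsu_calls"], cfg)
  invisible(list(assignment = asg, composition = comp, files = files))
}

#' Stage 3: transpositions, breakpoints and per-Mbp rates
#'
#' Runs the full comparison of a target genome against the units and writes
#' `breakpoint_groups.tsv`, `transposition_events.tsv` and a one-row
#' `rearrangement_summary.tsv` (breakpoints within units, per Mbp, single
#' and 2-3 marker transpositions, per Mbp). Without a length table the
#' denominators are inferred from marker coordinates and flagged so.
#'
#' @inheritParams lsu_assign
#' @param lengths Optional path to the target's sequence-length table (or
#'   tibble).
#' @param max_run Largest run still counted as a transposition.
#' @return Invisibly, a list with `assignment`, `composition`,
#'   `transpositions`, `breakpoints` and file paths.
#' @export
lsu_breakpoints <- function(units, target, out_dir, lengths = NULL,
                            max_run = 3,
                            min_component_markers = 5,
                            min_component_fraction = 0.05,
                            intact_fraction = 0.95,
                            drop_fragmented = FALSE, target_name = "target",
                            quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (inherits(units, "lsu_table")) units else read_lsu_table(units)
  records <- .as_records(target)
  lens <- .as_lengths(lengths)
  usable <- filter_usable(records, drop_fragmented = drop_fragmented,
                          quiet = quiet)
  if (is.null(lens)) lens <- infer_sequence_lengths(usable)
  asg <- assign_markers(usable, tab, target_name = target_name, quiet = quiet)
  comp <- classify_composition(
    composition_matrix(asg),
    min_component_markers = min_component_markers,
    min_component_fraction = min_component_fraction,
    intact_fraction = intact_fraction
  )
  ev <- detect_transpositions(asg, comp, max_run = max_run)
  bp <- count_breakpoints(asg, ev, lengths = lens)
  cfg <- list(target_name = target_name, max_run = max_run,
              min_component_markers = min_component_markers,
              min_component_fraction = min_component_fraction,
              intact_fraction = intact_fraction,
              lengths = if (isTRUE(attr(lens, "inferred"))) "inferred" else "supplied")
  files <- c(
    groups = file.path(out_dir, "breakpoint_groups.tsv"),
    events = file.path(out_dir, "transposition_events.tsv"),
    summary = file.path(out_dir, "rearrangement_summary.tsv")
  )
  .write_tsv(bp$groups, files["groups"], cfg)
  .write_tsv(ev, files["events"], cfg)
  .write_tsv(glance(bp), files["summary"], cfg)
  invisible(list(assignment = asg, composition = comp, transpositions = ev,
                 breakpoints = bp, files = files))
}

#' Stage 0: simulate an anchor/target genome pair with ground truth
#'
#' Generates a seeded anchor, draws a non-interacting event list at the
#' requested counts, applies it, and writes `anchor_full_table.tsv`,
#' `target_full_table.tsv`, the true sequence lengths of both genomes
#' (`*_lengths.tsv`, FASTA-index style), the resolved event log
#' (`truth.json`) and the configuration actually used
#' (`config_used.yaml`).
#'
#' @param out_dir Output directory.
#' @param config Optional path to a YAML file (or a named list) providing
#'   any of the arguments below; explicit arguments win.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length,jitter
#'   Anchor geometry, see [make_anchor()].
#' @param n_fusions,n_fissions,n_inversions,n_transpositions,n_losses,n_duplications
#'   Event counts, see [random_events()].
#' @param seed Integer seed driving both the anchor and the event draw.
#' @return Invisibly, a list with `anchor`, `target`, `truth` and file
#'   paths.
#' @export
lsu_simulate <- function(out_dir, config = NULL,
                         n_chromosomes = 31, markers_per_chromosome = 170,
                         chromosome_length = 2e7, jitter = 0.2,
                         n_fusions = 0, n_fissions = 0, n_inversions = 0,
                         n_transpositions = 0, n_losses = 0,
                         n_duplications = 0, seed = 1) {
  cfg <- as.list(environment())
  cfg$out_dir <- NULL
  cfg$config <- NULL
  if (!is.null(config)) {
    given <- if (is.character(config)) yaml::read_yaml(config) else config
    supplied <- names(match.call())[-1]
    for (k in names(given)) {
      if (!k %in% supplied && k %in% names(cfg)) cfg[[k]] <- given[[k]]
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anchor <- make_anchor(
    n_chromosomes = cfg$n_chromosomes,
    markers_per_chromosome = cfg$markers_per_chromosome,
    chromosome_length = cfg$chromosome_length,
    jitter = cfg$jitter, seed = cfg$seed
  )
  events <- random_events(
    anchor,
    n_fusions = cfg$n_fusions, n_fissions = cfg$n_fissions,
    n_inversions = cfg$n_inversions, n_transpositions = cfg$n_transpositions,
    n_losses = cfg$n_losses, n_duplications = cfg$n_duplications,
    seed = cfg$seed + 1L
  )
  sim <- apply_events(anchor, events)
  files <- c(
    anchor = file.path(out_dir, "anchor_full_table.tsv"),
    target = file.path(out_dir, "target_full_table.tsv"),
    anchor_lengths = file.path(out_dir, "anchor_lengths.tsv"),
    target_lengths = file.path(out_dir, "target_lengths.tsv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "config_used.yaml")
  )
  write_full_table(anchor, files["anchor"])
  write_full_table(sim$target, files["target"])
  al <- attr(anchor, "sim_lengths")
  writeLines(paste(al$sequence_id, format(al$length, scientific = FALSE, trim = TRUE),
                   sep = "\t"), files["anchor_lengths"])
  tl <- sim$truth$lengths
  writeLines(paste(tl$sequence_id, format(tl$length, scientific = FALSE, trim = TRUE),
                   sep = "\t"), files["target_lengths"])
  jsonlite::write_json(
    list(events = sim$truth$events,
         expected_signature = sim$truth$expected_signature,
         non_overlapping = sim$truth$non_overlapping),
    files["truth"], auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  yaml::write_yaml(cfg, files["config"])
  invisible(list(anchor = anchor, target = sim$target, truth = sim$truth,
                 files = files))
}

#' One-call comparison of two marker tables
#'
#' Convenience wrapper running the whole in-memory pipeline: filter both
#' genomes, define units on the anchor, assign the target, classify its
#' composition, detect transpositions and count breakpoints.
#'
#' @param anchor_records,target_records Marker-record tibbles.
#' @param lengths Optional target sequence-length tibble; inferred from
#'   marker coordinates when absent.
#' @param naming_policy,drop_fragmented,min_component_markers,min_component_fraction,intact_fraction,max_run
#'   Passed to the respective stages.
#' @param anchor_name,target_name Labels.
#' @return An object of class `lsu_analysis`: list with `lsu_table`,
#'   `assignment`, `composition`, `transpositions`, `breakpoints`.
#'   `glance()` gives the per-genome summary row.
#' @export
lsu_analyze <- function(anchor_records, target_records, lengths = NULL,
                        naming_policy = "by_sequence_suffix",
                        drop_fragmented = FALSE,
                        min_component_markers = 5,
                        min_component_fraction = 0.05,
                        intact_fraction = 0.95, max_run = 3,
                        anchor_name = "anchor", target_name = "target") {
  anchor_usable <- filter_usable(anchor_records,
                                 drop_fragmented = drop_fragmented, quiet = TRUE)
  target_usable <- filter_usable(target_records,
                                 drop_fragmented = drop_fragmented, quiet = TRUE)
  if (is.null(lengths)) lengths <- infer_sequence_lengths(target_usable)
  tab <- define_lsus(anchor_usable, naming_policy = naming_policy,
                     anchor_name = anchor_name)
  asg <- assign_markers(target_usable, tab, target_name = target_name,
                        quiet = TRUE)
  comp <- classify_composition(
    composition_matrix(asg),
    min_component_markers = min_component_markers,
    min_component_fraction = min_component_fraction,
    intact_fraction = intact_fraction
  )
  ev <- detect_transpositions(asg, comp, max_run = max_run)
  bp <- count_breakpoints(asg, ev, lengths = lengths)
  structure(
    list(lsu_table = tab, assignment = asg, composition = comp,
         transpositions = ev, breakpoints = bp),
    class = "lsu_analysis"
  )
}

#' @export
print.lsu_analysis <- function(x, ...) {
  print(x$composition)
  print(x$breakpoints)
  invisible(x)
}

#' @export
glance.lsu_analysis <- function(x, ...) {
  dplyr::bind_cols(glance(x$breakpoints),
                   glance(x$composition)[, c("n_single", "n_fusion", "n_split",
                                             "n_dispersed")])
}
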