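# Fixtures are built in code; nothing is read from disk.

# A small anchor for fast unit tests (3 chromosomes x 20 markers).
tiny_anchor <- function(n_chromosomes = 3, markers_per_chromosome = 20,
                        chromosome_length = 2e5, seed = 11) {
  make_anchor(n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              chromosome_length = chromosome_length, seed = seed)
}

# Randomized but valid marker-record tables for round-trip properties.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    status <- sample(c("Complete", "Duplicated", "Fragmented", "Missing"),
                     n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    miss <- status == "Missing"
    start <- sample.int(5e6, n, replace = TRUE)
    tibble::tibble(
      marker_id = sprintf("%dat7088", sample.int(999999, n)),
      status = status,
      sequence_id = ifelse(miss, NA, paste0("scaffold_", sample.int(20, n, TRUE))),
      start = ifelse(miss, NA, start),
      end = ifelse(miss, NA, start + sample.int(1e4, n, TRUE)),
      strand = ifelse(miss, "unknown", sample(c("+", "-", "unknown"), n, TRUE)),
      score = ifelse(miss, NA, round(runif(n, 100, 2000), 1)),
      length = ifelse(miss, NA, as.numeric(sample.int(2e4, n, TRUE)))
    )
  })
}

# Hand-built single-chromosome records whose anchor marker order is 1..m;
# reordering rows by a permutation and reassigning coordinates yields a
# target whose anchor ranks in target order equal that permutation.
perm_pair <- function(ranks) {
  m <- length(ranks)
  anchor <- tibble::tibble(
    marker_id = sprintf("m%04d", seq_len(m)), status = "Complete",
    sequence_id = "ChrA", start = 1000 * seq_len(m),
    end = 1000 * seq_len(m) + 500, strand = "+",
    score = NA_real_, length = 501
  )
  target <- anchor[ranks, ]
  target$start <- 1000 * seq_len(m)
  target$end <- target$start + 500
  list(anchor = anchor, target = target)
}

# Breakpoint total the pipeline reports for a single-group permutation.
pipeline_breakpoints_for_perm <- function(ranks) {
  p <- perm_pair(ranks)
  tab <- suppressWarnings(define_lsus(p$anchor))
  asg <- assign_markers(p$target, tab, quiet = TRUE)
  count_breakpoints(asg)$totals$breakpoints_within_lsus
}

# Full rearrange-stage readout for a simulated target against a prebuilt
# unit table (shared across many simulations for speed).
pipeline_readout <- function(lsu_table, target, max_run = 3) {
  usable <- filter_usable(target, quiet = TRUE)
  asg <- assign_markers(usable, lsu_table, quiet = TRUE)
  comp <- classify_composition(composition_matrix(asg))
  ev <- detect_transpositions(asg, comp, max_run = max_run)
  bp <- count_breakpoints(asg, ev)
  list(assignment = asg, composition = comp, transpositions = ev,
       breakpoints = bp)
}
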