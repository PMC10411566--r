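test_that("the breakpoint oracle counts non-consecutive adjacencies", {
  expect_equal(breakpoints_oracle(c(1, 2, 3)), 0L)
  expect_equal(breakpoints_oracle(c(2, 1, 3)), 1L)
  expect_equal(breakpoints_oracle(c(1, 2, 6, 5, 4, 3, 7, 8)), 2L)
  expect_equal(breakpoints_oracle(1L), 0L)
  expect_error(breakpoints_oracle(c(1, 1, 2)), "permutation")
  expect_error(breakpoints_oracle(c(2, 3, 4)), "permutation")
})

test_that("pipeline counting equals the oracle on single-group permutations", {
  # forced by the |delta rank| != 1 rule: one internal inversion leaves 2
  expect_equal(pipeline_breakpoints_for_perm(c(1, 2, 6, 5, 4, 3, 7, 8)), 2L)
  # whole-group reversal: descending ranks are still collinear (unsigned)
  expect_equal(pipeline_breakpoints_for_perm(20:1), 0L)
  withr::with_seed(13, {
    for (i in 1:50) {
      p <- sample(50)
      expect_equal(pipeline_breakpoints_for_perm(p), breakpoints_oracle(p))
    }
  })
})

test_that("re-ranking makes counts robust to losses inside collinear runs", {
  # drop markers strictly inside collinear segments of an inverted block
  full <- c(1, 2, 8, 7, 6, 5, 4, 3, 9, 10)
  expect_equal(pipeline_breakpoints_for_perm(full), 2L)
  dropped <- setdiff(full, c(6, 5)) # interior of the inverted segment
  renormalized <- match(dropped, sort(dropped))
  expect_equal(pipeline_breakpoints_for_perm(renormalized), 2L)
})

test_that("transposition runs are found by a maximal-run scan with size cap", {
  anchor <- make_anchor(n_chromosomes = 4, markers_per_chromosome = 60,
                        chromosome_length = 6e5, seed = 17)
  tab <- define_lsus(anchor)

  # identity: no foreign runs anywhere
  out0 <- pipeline_readout(tab, anchor)
  expect_equal(nrow(out0$transpositions), 0)

  # two adjacent foreign markers inserted into another chromosome
  sim <- apply_events(anchor, list(ev_transposition("Chr2", 10, 2, "Chr3", 25)))
  out <- pipeline_readout(tab, sim$target)
  ev <- out$transpositions
  expect_equal(nrow(ev), 1)
  expect_equal(ev$run_size, 2L)
  expect_equal(ev$kind, "transposition")
  expect_equal(ev$lsu_id, "LSU_2")
  expect_equal(ev$target_sequence, "Chr3")
  expect_setequal(ev$marker_ids[[1]], sim$truth$events[[1]]$marker_ids)

  # independent brute-force scan over the assignment
  a <- out$assignment[!is.na(out$assignment$lsu_id), ]
  a <- a[a$target_sequence == "Chr3", ]
  a <- a[order(a$target_rank), ]
  foreign <- a$lsu_id != "LSU_3"
  r <- rle(foreign)
  expect_equal(sum(r$values), 1)
  expect_equal(r$lengths[r$values], 2)

  # runs longer than max_run become translocated segments, not transpositions
  # (kept below min_component_markers so the segment is still "foreign")
  sim2 <- apply_events(anchor, list(ev_transposition("Chr2", 10, 4, "Chr3", 25)))
  ev2 <- pipeline_readout(tab, sim2$target)$transpositions
  expect_equal(ev2$kind, "translocated_segment")
  expect_equal(ev2$run_size, 4L)
  bp2 <- count_breakpoints(pipeline_readout(tab, sim2$target)$assignment,
                           ev2)
  expect_equal(bp2$totals$transpositions_single +
                 bp2$totals$transpositions_grouped, 0L)

  expect_error(detect_transpositions(out$assignment, out$composition,
                                     max_run = 0), "at least 1")
})

test_that("transposed markers are excluded from breakpoint groups", {
  anchor <- make_anchor(n_chromosomes = 4, markers_per_chromosome = 60,
                        chromosome_length = 6e5, seed = 17)
  tab <- define_lsus(anchor)
  sim <- apply_events(anchor, list(ev_transposition("Chr2", 10, 2, "Chr3", 25)))
  out <- pipeline_readout(tab, sim$target)
  bp <- out$breakpoints
  expect_equal(bp$totals$breakpoints_within_lsus, 0L)
  expect_equal(bp$totals$transpositions_grouped, 1L)
  # the moved run forms no (Chr3, LSU_2) group once excluded
  expect_false(any(bp$groups$target_sequence == "Chr3" &
                     bp$groups$lsu_id == "LSU_2"))
  # without exclusion the group exists (still collinear, so 0 breakpoints)
  bp_raw <- count_breakpoints(out$assignment)
  expect_true(any(bp_raw$groups$target_sequence == "Chr3" &
                    bp_raw$groups$lsu_id == "LSU_2"))
})

test_that("clean fusions and fissions leave no within-unit breakpoints", {
  anchor <- make_anchor(n_chromosomes = 6, markers_per_chromosome = 80,
                        chromosome_length = 8e5, seed = 23)
  tab <- define_lsus(anchor)
  sim <- apply_events(anchor, list(ev_fusion("Chr1", "Chr4"),
                                   ev_fission("Chr2", 40)))
  out <- pipeline_readout(tab, sim$target)
  expect_equal(out$breakpoints$totals$breakpoints_within_lsus, 0L)
  expect_equal(nrow(out$transpositions), 0)
})

test_that("per-Mbp rates are plain arithmetic with provenance", {
  lens <- tibble::tibble(sequence_id = c("a", "b"), length = c(6e7, 4e7))
  attr(lens, "inferred") <- FALSE
  r <- per_mbp(10, lens)
  expect_equal(as.numeric(r), 0.1)
  expect_equal(attr(r, "provenance"), "supplied")
  expect_equal(as.numeric(per_mbp(0, lens)), 0)
  expect_equal(as.numeric(per_mbp(5, lens, sequences = "a")), 5 / 60)
  expect_error(per_mbp(1, lens, sequences = "zzz"), "denominator")

  inf <- lens
  attr(inf, "inferred") <- TRUE
  expect_equal(attr(per_mbp(1, inf), "provenance"), "inferred")

  # flows into the report when lengths are attached
  anchor <- tiny_anchor()
  tab <- define_lsus(anchor)
  asg <- assign_markers(anchor, tab, quiet = TRUE)
  bp <- count_breakpoints(asg, lengths = infer_sequence_lengths(anchor))
  expect_true(bp$lengths_inferred)
  expect_equal(bp$rates$breakpoints_per_mbp, 0)
  expect_s3_class(autoplot(bp), "ggplot")
  expect_equal(glance(bp)$lengths_inferred, TRUE)
})
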