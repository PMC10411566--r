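test_that("anchor generation is deterministic and well formed", {
  a <- make_anchor(n_chromosomes = 31, markers_per_chromosome = 170,
                   chromosome_length = 2e7, seed = 1)
  expect_equal(nrow(a), 31 * 170)
  expect_true(all(a$status == "Complete"))
  expect_equal(length(unique(a$sequence_id)), 31)
  expect_true("ChrZ" %in% a$sequence_id)
  for (s in unique(a$sequence_id)) {
    st <- a$start[a$sequence_id == s]
    expect_true(all(diff(st) > 0))
  }
  expect_true(all(a$end <= 2e7))
  b <- make_anchor(n_chromosomes = 31, markers_per_chromosome = 170,
                   chromosome_length = 2e7, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_anchor(seed = 2)))
  expect_error(make_anchor(chromosome_length = 10, markers_per_chromosome = 50),
               "exceed")
})

test_that("an empty event list reproduces the anchor exactly", {
  a <- tiny_anchor()
  sim <- apply_events(a, list())
  expect_equal(as.data.frame(sim$target), as.data.frame(a))
  expect_true(sim$truth$non_overlapping)
  expect_equal(sim$truth$expected_signature$breakpoints_total, 0L)
})

test_that("fusion concatenates both marker blocks on one sequence", {
  a <- tiny_anchor()
  sim <- apply_events(a, list(ev_fusion("Chr1", "Chr2")))
  tgt <- sim$target
  expect_equal(length(unique(tgt$sequence_id)), 2)
  fused <- tgt[tgt$sequence_id == "Chr1--Chr2", ]
  fused <- fused[order(fused$start), ]
  expect_equal(fused$marker_id,
               c(a$marker_id[a$sequence_id == "Chr1"],
                 a$marker_id[a$sequence_id == "Chr2"]))
  expect_equal(sim$truth$expected_signature$fusions[[1]]$units,
               c("LSU_1", "LSU_2"))
})

test_that("five internal inversions on one chromosome leave ten breakpoints", {
  a <- make_anchor(n_chromosomes = 3, markers_per_chromosome = 100,
                   chromosome_length = 1e6, seed = 5)
  ev <- list(
    ev_inversion("Chr1", 5, 12), ev_inversion("Chr1", 20, 30),
    ev_inversion("Chr1", 40, 44), ev_inversion("Chr1", 60, 75),
    ev_inversion("Chr1", 80, 95)
  )
  sim <- apply_events(a, ev)
  expect_equal(sim$truth$expected_signature$breakpoints_total, 10L)
  tab <- define_lsus(a)
  out <- pipeline_readout(tab, sim$target)
  expect_equal(out$breakpoints$totals$breakpoints_within_lsus, 10L)
})

test_that("event validation names the offending event", {
  a <- tiny_anchor()
  expect_error(apply_events(a, list(ev_inversion("Chr9", 2, 5))),
               "event 1 \\(inversion\\).*Chr9")
  expect_error(apply_events(a, list(ev_inversion("Chr1", 5, 200))),
               "event 1")
  expect_error(apply_events(a, list(ev_fission("Chr1", 20))), "out of range")
  expect_error(apply_events(a, list(ev_transposition("Chr1", 1, 2, "Chr1", 5))),
               "must differ")
  expect_error(apply_events(a, list(ev_loss(c("nope")))), "not present")
})

test_that("interacting event lists carry no analytic signature", {
  a <- tiny_anchor()
  sim <- apply_events(a, list(ev_inversion("Chr1", 4, 10),
                              ev_inversion("Chr1", 9, 15)))
  expect_false(sim$truth$non_overlapping)
  expect_null(sim$truth$expected_signature)
})

test_that("losses become Missing rows, duplications two Duplicated lines", {
  a <- tiny_anchor()
  ids <- a$marker_id[a$sequence_id == "Chr1"][5:6]
  dup_id <- a$marker_id[a$sequence_id == "Chr2"][8]
  sim <- apply_events(a, list(ev_loss(ids), ev_duplication(dup_id)))
  tgt <- sim$target
  expect_equal(tgt$status[match(ids, tgt$marker_id)], rep("Missing", 2))
  expect_true(all(is.na(tgt$start[tgt$marker_id %in% ids])))
  expect_equal(sum(tgt$marker_id == dup_id), 2)
  expect_true(all(tgt$status[tgt$marker_id == dup_id] == "Duplicated"))
  # and the pipeline simply drops them
  tab <- define_lsus(a)
  out <- pipeline_readout(tab, tgt)
  expect_equal(out$breakpoints$totals$breakpoints_within_lsus, 0L)
  expect_false(any(c(ids, dup_id) %in% out$assignment$marker_id))
})

test_that("fractional loss picks are systematic and deterministic", {
  a <- tiny_anchor()
  sim <- apply_events(a, list(ev_loss(fraction = 0.1)))
  n_lost <- sum(sim$target$status == "Missing")
  expect_equal(n_lost, 6) # every 10th of 60 markers
  sim2 <- apply_events(a, list(ev_loss(fraction = 0.1)))
  expect_identical(sim$target, sim2$target)
})

test_that("random event draws are reproducible and always applicable", {
  a <- make_anchor(n_chromosomes = 10, markers_per_chromosome = 40,
                   chromosome_length = 4e5, seed = 2)
  expect_length(random_events(a, seed = 1), 0)
  e1 <- random_events(a, n_fusions = 1, n_inversions = 3, seed = 7)
  e2 <- random_events(a, n_fusions = 1, n_inversions = 3, seed = 7)
  expect_identical(e1, e2)
  expect_error(random_events(a, n_fusions = 20, seed = 1),
               "cannot be satisfied")

  for (s in 1:100) {
    ev <- random_events(a, n_fusions = 1, n_fissions = 1, n_inversions = 2,
                        n_transpositions = 1, n_losses = 3,
                        n_duplications = 1, seed = s)
    sim <- apply_events(a, ev)
    expect_true(sim$truth$non_overlapping)
  }
})

test_that("identical seeds give byte-identical emitted tables", {
  run <- function() {
    a <- make_anchor(n_chromosomes = 8, markers_per_chromosome = 30,
                     chromosome_length = 3e5, seed = 4)
    ev <- random_events(a, n_fusions = 1, n_inversions = 2,
                        n_transpositions = 1, seed = 9)
    write_full_table(apply_events(a, ev)$target)
  }
  expect_identical(run(), run())
})
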