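test_that("filtering drops Missing and every line of Duplicated markers", {
  rec <- tibble::tibble(
    marker_id = c("a", "b", "c", "c", "d"),
    status = c("Complete", "Missing", "Duplicated", "Duplicated", "Fragmented"),
    sequence_id = c("Chr1", NA, "Chr1", "Chr2", "Chr1"),
    start = c(10, NA, 50, 60, 90), end = c(20, NA, 55, 70, 95),
    strand = c("+", "unknown", "+", "-", "+"),
    score = NA_real_, length = NA_real_
  )
  kept <- filter_usable(rec, quiet = TRUE)
  expect_equal(kept$marker_id, c("a", "d"))
  expect_equal(kept$status, c("Complete", "Fragmented"))
  expect_equal(filter_usable(rec, drop_fragmented = TRUE, quiet = TRUE)$marker_id, "a")
  expect_message(filter_usable(rec), "removed 1 Missing, 2 Duplicated")

  all_missing <- rec[rec$status == "Missing", ]
  expect_error(filter_usable(all_missing, quiet = TRUE), "no usable markers")
})

test_that("unit definition sorts by position and numbers chromosomes, Z last", {
  anchor <- make_anchor(n_chromosomes = 31, markers_per_chromosome = 10,
                        chromosome_length = 1e5, seed = 3)
  tab <- define_lsus(anchor)
  expect_s3_class(tab, "lsu_table")
  expect_length(attr(tab, "lsu_names"), 31)
  map <- attr(tab, "lsu_map")
  expect_equal(unname(map["ChrZ"]), "LSU_31")
  expect_equal(unname(map["Chr2"]), "LSU_2")
  expect_equal(unname(map["Chr30"]), "LSU_30")

  # shuffled input: ranks follow coordinates, not input order
  six <- tibble::tibble(
    marker_id = letters[1:6], status = "Complete",
    sequence_id = rep(c("Chr1", "Chr2"), each = 3),
    start = c(300, 100, 200, 20, 30, 10), end = c(310, 110, 210, 25, 35, 15),
    strand = "+", score = NA_real_, length = NA_real_
  )
  shuffled <- six[c(4, 1, 6, 3, 2, 5), ]
  t2 <- define_lsus(shuffled)
  expect_equal(t2$marker_id[t2$lsu_id == "LSU_1"], c("b", "c", "a"))
  expect_equal(t2$marker_id[t2$lsu_id == "LSU_2"], c("f", "d", "e"))
  expect_equal(t2$anchor_rank, rep(1:3, 2))
})

test_that("ranks are contiguous and monotone against a brute-force sort", {
  withr::with_seed(5, {
    rec <- tibble::tibble(
      marker_id = sprintf("m%03d", 1:100), status = "Complete",
      sequence_id = sample(paste0("Chr", 1:5), 100, replace = TRUE),
      start = sample.int(1e6, 100), strand = "+",
      score = NA_real_, length = NA_real_
    )
    rec$end <- rec$start + 100
  })
  tab <- define_lsus(rec)
  for (u in unique(tab$lsu_id)) {
    g <- tab[tab$lsu_id == u, ]
    expect_equal(sort(g$anchor_rank), seq_len(nrow(g)))
    # independent oracle: plain order() on the raw records of that sequence
    seq_id <- g$anchor_sequence[1]
    raw <- rec[rec$sequence_id == seq_id, ]
    expect_equal(g$marker_id, raw$marker_id[order(raw$start, raw$end, raw$marker_id)])
    expect_true(all(diff(g$anchor_start) > 0))
  }
})

test_that("naming policies and degenerate anchors behave as documented", {
  anchor <- tiny_anchor()
  lens <- attr(anchor, "sim_lengths")
  lens$length <- c(100, 300, 200) # Chr2 longest
  t_len <- define_lsus(anchor, naming_policy = "by_length_desc", lengths = lens)
  expect_equal(unname(attr(t_len, "lsu_map")[lens$sequence_id[order(-lens$length)]]),
               paste0("LSU_", 1:3))
  expect_error(define_lsus(anchor, naming_policy = "by_length_desc"),
               "requires")
  one <- anchor[anchor$sequence_id == "Chr1", ]
  expect_warning(define_lsus(one), "fewer than 2")
  dup <- rbind(anchor, anchor[1, ])
  expect_error(define_lsus(dup), "more than once")
})

test_that("unit tables survive serialization to TSV", {
  tab <- define_lsus(tiny_anchor(), anchor_name = "toy")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lsu_table(tab, f)
  back <- read_lsu_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "anchor_name"), "toy")
  expect_equal(attr(back, "lsu_names"), attr(tab, "lsu_names"))
  expect_equal(attr(back, "lsu_map"), attr(tab, "lsu_map"))
})

test_that("coverage summary equals brute-force group statistics", {
  single <- tibble::tibble(
    marker_id = "x", status = "Complete", sequence_id = "Chr1",
    start = 100, end = 200, strand = "+", score = NA_real_, length = NA_real_
  )
  cov1 <- coverage_summary(single)
  expect_equal(cov1$from_pos, 100)
  expect_equal(cov1$to_pos, 200)
  expect_equal(cov1$n_markers, 1L)

  anchor <- tiny_anchor()
  cov <- coverage_summary(anchor, lengths = attr(anchor, "sim_lengths"))
  for (i in seq_len(nrow(cov))) {
    g <- anchor[anchor$sequence_id == cov$sequence_id[i], ]
    expect_equal(cov$from_pos[i], min(g$start))
    expect_equal(cov$to_pos[i], max(g$end))
    expect_equal(cov$n_markers[i], nrow(g))
  }
  expect_equal(cov$size_bp, rep(2e5, 3))
})

test_that("assignment joins by marker identity and ranks along the target", {
  anchor <- tiny_anchor()
  tab <- define_lsus(anchor)

  # identity: anchor against itself
  asg <- assign_markers(anchor, tab, quiet = TRUE)
  expect_equal(sum(is.na(asg$lsu_id)), 0)
  by_seq <- split(asg, asg$target_sequence)
  for (g in by_seq) expect_equal(g$anchor_rank[order(g$target_rank)],
                                 seq_len(nrow(g)))

  # a marker unknown to the table stays unassigned
  extra <- anchor[1, ]
  extra$marker_id <- "NOVELat0000"
  extra$start <- 99999
  extra$end <- 99999 + 100
  asg2 <- assign_markers(rbind(anchor, extra), tab, quiet = TRUE)
  expect_equal(sum(is.na(asg2$lsu_id)), 1)
  expect_equal(attr(asg2, "n_unassigned"), 1L)
  expect_message(assign_markers(rbind(anchor, extra), tab), "unassigned")

  # shuffled target equals a brute-force dictionary lookup
  shuf <- anchor[sample.int(nrow(anchor)), ]
  asg3 <- assign_markers(shuf, tab, quiet = TRUE)
  dict <- stats::setNames(tab$lsu_id, tab$marker_id)
  expect_equal(asg3$lsu_id, unname(dict[asg3$marker_id]))

  # zero overlap is an error
  alien <- anchor
  alien$marker_id <- paste0("X", alien$marker_id)
  expect_error(assign_markers(alien, tab, quiet = TRUE), "no overlap")
})

test_that("hit counts equal a brute-force tally and conserve totals", {
  anchor <- make_anchor(n_chromosomes = 5, markers_per_chromosome = 200,
                        chromosome_length = 2e6, seed = 9)
  tab <- define_lsus(anchor)
  ev <- random_events(anchor, n_fusions = 1, n_transpositions = 1, seed = 2)
  target <- apply_events(anchor, ev)$target
  asg <- assign_markers(filter_usable(target, quiet = TRUE), tab, quiet = TRUE)
  comp <- composition_matrix(asg)

  expect_equal(sum(comp$matrix), sum(!is.na(asg$lsu_id)))
  a <- asg[!is.na(asg$lsu_id), ]
  oracle <- table(a$target_sequence, a$lsu_id)
  for (s in rownames(oracle)) {
    for (u in colnames(oracle)) {
      expect_equal(comp$matrix[s, u], unname(oracle[s, u]))
    }
  }
  # identity matrix is diagonal up to row/column naming
  comp_id <- composition_matrix(assign_markers(anchor, tab, quiet = TRUE))
  M <- comp_id$matrix
  expect_true(all(rowSums(M > 0) == 1) && all(colSums(M > 0) == 1))
})
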