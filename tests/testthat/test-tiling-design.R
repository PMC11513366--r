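test_that("flank expansion reproduces the printed outer region from the locus", {
  inner <- parse_region_string("chr1:68,428,822-68,449,954")
  outer <- parse_region_string("chr1:68,423,822-68,454,954")
  expect_equal(region_length(inner), 21133)
  ex <- expand_with_flanks(inner, 5000)
  expect_equal(ex[c("seq_name", "start", "end")],
               outer[c("seq_name", "start", "end")])
  expect_equal(region_length(ex), 31133)

  # flank 0 is the identity; flanks past the origin are rejected
  expect_equal(expand_with_flanks(inner, 0)[1:3], inner[1:3])
  expect_error(expand_with_flanks(gregion("chr1", 0, 100), 5), "origin")
})

test_that("tiling partitions a region into ceil(length/block) near-equal blocks", {
  t4 <- build_tiles(gregion("chr1", 0, 31133))
  expect_equal(nrow(t4), 4)
  expect_equal(t4$start, c(0, 7783, 15567, 23350))
  expect_equal(t4$end, c(7783, 15567, 23350, 31133))

  expect_equal(nrow(build_tiles(gregion("chr1", 0, 10000))), 1)
  expect_equal(nrow(build_tiles(gregion("chr1", 0, 20001))), 3)
  expect_error(build_tiles(gregion("chr1", 0, 10000), block_size = 500),
               "block_size")

  # contiguous and exhaustive for arbitrary offsets
  t3 <- build_tiles(gregion("chr1", 123, 123 + 25000))
  expect_equal(t3$start[-1], t3$end[-nrow(t3)])
  expect_equal(t3$start[1], 123)
  expect_equal(t3$end[nrow(t3)], 123 + 25000)
})

test_that("pair selection prefers efficiency and errors on empty tiles", {
  cand <- data.frame(
    seq_name = "chrS",
    protospacer = c("CCCGTACGTAAGCATCAGTG", "GTATCAATGTTCTTCCTGGG",
                    "GGTATCTAATTACATGTGAG"),
    pam = "TGG",
    strand = c("-", "-", "+"),
    protospacer_start = c(100, 400, 9000),
    cut_pos = c(120, 420, 9020),
    stringsAsFactors = FALSE
  )
  cand <- add_guide_metrics(cand, offtargets = FALSE)
  cand[, paste0("mm", 0:3)] <- 0
  cand$self_complementarity <- 0
  cand$efficiency <- c(0.8, 0.3, 0.6)
  tile <- list(start = 0, end = 10000)
  genome <- make_reference(1000, 0.4, seed = 1)  # no matching sites: mm stays 0

  pair <- select_pair_for_tile(tile, cand, genome, window_max = 10000)
  expect_equal(pair$minus$efficiency, 0.8)  # higher-efficiency minus guide wins
  expect_equal(pair$plus$strand, "+")

  # no plus-strand candidate near the right edge -> error
  expect_error(
    select_pair_for_tile(list(start = 0, end = 30000), cand[1:2, ], genome),
    "no criteria-passing"
  )
})

test_that("a 31 kb design yields 4 interleaved opposite-strand pairs meeting all rules", {
  d <- std_design()
  g <- d$guides
  expect_equal(max(g$pair), 4)
  expect_equal(nrow(g), 8)
  expect_true(all(passes_criteria(g, d$criteria)))
  expect_true(all(g$gc_percent >= 30 & g$gc_percent <= 80))
  expect_true(all(g$self_complementarity == 0))
  expect_true(all(g$mm0 + g$mm1 + g$mm2 + g$mm3 < 10))
  expect_true(all(g$efficiency >= 0.2))
  # pairs sit on opposite strands and cuts interleave along the region
  for (k in 1:4) {
    expect_setequal(g$strand[g$pair == k], c("+", "-"))
  }
  cuts <- g$cut_pos[order(g$cut_pos)]
  expect_true(all(diff(cuts) > 0))
  expect_lt(max(diff(cuts)), 10000)
  expect_identical(g$strand[order(g$cut_pos)], rep(c("-", "+"), 4))

  # deterministic: same reference in, same design out
  d2 <- design_tiling(std_ref(), gregion("chrS", 0, 31133), flank = 0)
  expect_identical(d$guides, d2$guides)
})

test_that("a 10 kb region designs a single pair", {
  ref <- make_reference(10000, 0.4, seed = 7)
  d <- design_tiling(ref, gregion("chrS", 0, 10000), flank = 0)
  expect_equal(nrow(d$guides), 2)
  expect_setequal(d$guides$strand, c("+", "-"))
})

test_that("pool layouts partition the guides per scheme", {
  d <- std_design()
  g <- d$guides

  brick <- assign_pools(d, "bricklayer")
  expect_setequal(brick$pools$A, g$name[g$pair %in% c(1, 3)])
  expect_setequal(brick$pools$B, g$name[g$pair %in% c(2, 4)])

  hw <- assign_pools(d, "highway")
  expect_setequal(hw$pools$C, g$name[g$strand == "-"])
  expect_setequal(hw$pools$D, g$name[g$strand == "+"])

  for (lay in list(brick, hw)) {
    pooled <- unlist(lay$pools)
    expect_equal(length(pooled), nrow(g))       # disjoint...
    expect_setequal(pooled, g$name)             # ...and exhaustive
  }
  # no two guides of a pair, nor adjacent pairs, share a bricklayer pool
  for (k in 1:4) {
    pair_guides <- g$name[g$pair == k]
    expect_length(intersect(pair_guides, brick$pools$A), 2 * (k %% 2))
  }
  expect_error(assign_pools(d, "zigzag"))

  # single-pair design: pool B legitimately empty
  ref1 <- make_reference(10000, 0.4, seed = 7)
  d1 <- design_tiling(ref1, gregion("chrS", 0, 10000), flank = 0)
  b1 <- assign_pools(d1, "bricklayer")
  expect_length(b1$pools$A, 2)
  expect_length(b1$pools$B, 0)
})

test_that("design report tabulates guides with pair distances and pools", {
  d <- std_design()
  rep <- design_report(d, list(assign_pools(d, "bricklayer"),
                               assign_pools(d, "highway")))
  expect_equal(nrow(rep$guides), 8)
  expect_lt(rep$max_adjacent_distance, 10000)
  per_pair <- tapply(d$guides$cut_pos, d$guides$pair, function(x) diff(range(x)))
  expect_equal(rep$mean_pair_distance, mean(per_pair))
  expect_true(all(rep$guides$pool_bricklayer %in% c("A", "B")))
  expect_true(all(rep$guides$pool_highway %in% c("C", "D")))
  expect_equal(nchar(rep$guides$sequence), rep(23, 8))

  # TSV round trip reconstructs the guide table
  p <- tempfile(fileext = ".tsv")
  write_design_report(rep, p)
  back <- read_design(p)
  expect_equal(back$name, rep$guides$name)
  expect_equal(back$cut_pos, rep$guides$cut_pos)
  expect_equal(back$protospacer, substr(rep$guides$sequence, 1, 20))
})
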