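test_that("with certain cuts and no background, every read starts at a cut site", {
  d <- std_design()
  g <- d$guides
  g$efficiency <- 1
  cfg <- sim_config(n_molecules = 30, background_rate = 0, seed = 3)
  reads <- simulate_reads(std_ref(), g, cfg)
  expect_true(all(reads$origin == "cut"))
  anchors <- ifelse(reads$direction == "fwd", reads$start, reads$end)
  expect_true(all(anchors %in% g$cut_pos))
  # minus guides read forward, plus guides read backward
  role <- g$strand[match(reads$guide_name, g$name)]
  expect_true(all(reads$direction[role == "-"] == "fwd"))
  expect_true(all(reads$direction[role == "+"] == "rev"))
})

test_that("with zero efficiency and no background, no reads are produced", {
  g <- std_design()$guides
  g$efficiency <- 0
  reads <- simulate_reads(std_ref(), g,
                          sim_config(n_molecules = 20, background_rate = 0,
                                     seed = 3))
  expect_equal(nrow(reads), 0)
})

test_that("read counts follow the binomial expectation of the cut model", {
  d <- std_design()
  cfg <- sim_config(seed = 7)  # defaults: 1000 molecules
  reads <- simulate_reads(std_ref(), d, cfg)
  expected <- cfg$n_molecules *
    (sum(d$guides$efficiency) + cfg$background_rate)
  expect_lt(abs(nrow(reads) - expected), 3 * sqrt(expected))
})

test_that("the Qscore filter keeps the boundary and preserves order", {
  reads <- data.frame(read_id = c("a", "b", "c"), start = 0, end = 10,
                      direction = "fwd", mean_q = c(8.9, 9.0, 15),
                      origin = "cut", guide_name = NA)
  kept <- apply_qscore_filter(reads)
  expect_equal(kept$read_id, c("b", "c"))
  expect_equal(nrow(apply_qscore_filter(reads, 0)), 3)
  expect_equal(nrow(apply_qscore_filter(reads[0, ])), 0)
})

test_that("median cut-read length sits near the 8 kb lognormal median", {
  wd <- wide_design()
  reads <- simulate_reads(wd$ref, wd$design, sim_config(seed = 5))
  cut_lengths <- with(reads[reads$origin == "cut", ], end - start)
  expect_gt(length(cut_lengths), 500)
  expect_lt(abs(median(cut_lengths) - 8000) / 8000, 0.10)
})

test_that("each cut's read pile decays monotonically away from the cut", {
  wd <- wide_design()
  reads <- simulate_reads(wd$ref, wd$design, sim_config(seed = 11))
  g <- wd$design$guides
  reg <- gregion("chrS", 0, 40000)
  for (i in which(g$strand == "-")) {
    own <- reads[!is.na(reads$guide_name) & reads$guide_name == g$name[i], ]
    prof <- depth_profile(own, reg)
    at_cut <- prof$depth[g$cut_pos[i] + 1]
    downstream <- prof$depth[min(g$cut_pos[i] + 9000, 39999) + 1]
    expect_gt(at_cut, downstream)
    # non-increasing along the read direction
    seg <- prof$depth[(g$cut_pos[i] + 1):min(g$cut_pos[i] + 9000, 40000)]
    expect_true(all(diff(seg) <= 0))
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  d <- std_design()
  cfg <- sim_config(n_molecules = 60, seed = 42)
  r1 <- simulate_reads(std_ref(), d, cfg)
  r2 <- simulate_reads(std_ref(), d, cfg)
  expect_identical(r1, r2)

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emit_fastq(r1[1:25, ], std_ref(), f1, seed = 9)
  emit_fastq(r2[1:25, ], std_ref(), f2, seed = 9)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  t1 <- tempfile(); t2 <- tempfile()
  emit_truth_alignments(r1, t1); emit_truth_alignments(r2, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("FASTQ output matches read count, lengths and error rate", {
  d <- std_design()
  reads <- simulate_reads(std_ref(), d,
                          sim_config(n_molecules = 20, seed = 2))
  reads <- reads[1:30, ]
  reads$mean_q <- 20  # 1% substitution rate
  fq <- tempfile(fileext = ".fastq")
  emit_fastq(reads, std_ref(), fq, seed = 6)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(back), 30)
  expect_equal(Biostrings::width(back), reads$end - reads$start)

  # observed mismatch rate to the reference near 1%
  s <- as.character(std_ref()[[1]])
  mism <- 0; tot <- 0
  for (i in seq_len(30)) {
    truth <- substr(s, reads$start[i] + 1, reads$end[i])
    obs <- as.character(back[[i]])
    if (reads$direction[i] == "rev") {
      obs <- as.character(Biostrings::reverseComplement(back[[i]]))
    }
    mism <- mism + sum(charToRaw(truth) != charToRaw(obs))
    tot <- tot + nchar(truth)
  }
  expect_gt(mism / tot, 0.005)
  expect_lt(mism / tot, 0.015)
})

test_that("truth alignments are BED-compatible and round-trip", {
  d <- std_design()
  reads <- simulate_reads(std_ref(), d,
                          sim_config(n_molecules = 10, seed = 8))
  p <- tempfile(fileext = ".bed")
  emit_truth_alignments(reads, p)
  # consumable as BED (first three columns define valid intervals)
  as_bed <- read_bed(p)
  expect_length(as_bed, nrow(reads))
  expect_true(all(vapply(as_bed, function(r) r$end > r$start, logical(1))))
  # full fidelity through the dedicated reader
  back <- read_truth_alignments(p)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$start, reads$start)
  expect_equal(back$end, reads$end)
  expect_equal(back$direction, reads$direction)
  expect_equal(back$origin, reads$origin)
  expect_equal(back$mean_q, round(reads$mean_q, 2))
})
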