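test_that("PAM scanning finds planted candidates on both strands", {
  # single + candidate in a minimal 23-mer
  cand <- enumerate_candidates("AAAAAAAAAAAAAAAAAAAAAGG")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$protospacer, "AAAAAAAAAAAAAAAAAAAA")
  expect_equal(cand$pam, "AGG")
  expect_equal(cand$strand, "+")
  expect_equal(cand$protospacer_start, 0)
  expect_equal(cand$cut_pos, 17)

  # no GG or CC dinucleotide anywhere -> no candidates
  none <- enumerate_candidates(strrep("AGAT", 10))
  expect_equal(nrow(none), 0)

  # windows containing N are discarded
  withN <- enumerate_candidates("AAAAAAAAAANAAAAAAAAAAGG")
  expect_equal(nrow(withN), 0)
})

test_that("candidate enumeration agrees with a window-scan oracle", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  cand <- enumerate_candidates(s)
  orc <- oracle_candidates(s)
  expect_equal(nrow(cand), length(orc))
  okey <- sort(vapply(orc, function(o) paste(o$strand, o$start, o$proto), ""))
  ckey <- sort(paste(cand$strand, cand$protospacer_start, cand$protospacer))
  expect_equal(ckey, okey)
  # sorted by cut position, + before - on ties
  expect_true(!is.unsorted(cand$cut_pos))
})

test_that("enumeration on the reverse complement mirrors strands and coordinates", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  L <- nchar(s)
  fwd <- enumerate_candidates(s)
  rev <- enumerate_candidates(oracle_revcomp(s))
  expect_equal(nrow(fwd), nrow(rev))
  # a + candidate with footprint [s, s+20) maps to a - candidate with
  # footprint start L - s - 20, same protospacer
  mirror <- data.frame(
    protospacer = rev$protospacer,
    strand = ifelse(rev$strand == "+", "-", "+"),
    protospacer_start = L - rev$protospacer_start - 20
  )
  key <- function(d) sort(paste(d$strand, d$protospacer_start, d$protospacer))
  expect_equal(key(fwd), key(mirror))
})

test_that("GC percent matches the published guide values and complement identity", {
  expect_equal(gc_percent("GTATCAATGTTCTTCCTGGG"), 45)
  expect_equal(gc_percent("CCCGTACGTAAGCATCAGTG"), 55)
  expect_equal(gc_percent("GGTATCTAATTACATGTGAG"), 35)
  expect_equal(gc_percent("AAAAAAAAAAAAAAAAAAAA"), 0)
  expect_error(gc_percent("ACGT"), "20 nt")
  expect_error(gc_percent("NAAAAAAAAAAAAAAAAAAA"), "A/C/G/T")

  set.seed(21)
  for (i in 1:20) {
    p <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    at <- sum(strsplit(p, "")[[1]] %in% c("A", "T")) / 20
    expect_equal(gc_percent(p), 100 * (1 - at))
  }
})

test_that("self-complementarity counts hairpin seeds and backbone folds", {
  expect_equal(self_complementarity("CCCGTACGTAAGCATCAGTG"), 0)
  # AAAA (pos 1) pairs with TTTT (pos 12), loop >= 3
  expect_gte(self_complementarity("AAAACGCGCGCTTTTGCATG"), 1)
  expect_error(self_complementarity("AAAACGCGCGCTTTTGCAT"), "20 nt")

  # with an empty backbone only intramolecular pairs remain
  set.seed(3)
  for (i in 1:20) {
    p <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    expect_lte(self_complementarity(p, backbone = ""),
               self_complementarity(p))
  }

  # backbone fold: protospacer 4-mer whose revcomp occurs in the backbone
  # ("AGGC" in default backbone is revcomp of "GCCT")
  with_fold <- self_complementarity("GCCTATATATATATATATAT")
  only_intra <- self_complementarity("GCCTATATATATATATATAT", backbone = "")
  expect_equal(with_fold - only_intra, 1)
})

test_that("off-target counts on planted genomes match construction and brute force", {
  proto <- "GTATCAATGTTCTTCCTGGG"

  # genome holding only the on-target site -> all strata zero
  ref1 <- make_reference(
    1000, 0.3, seed = 101,
    planted_sites = data.frame(protospacer = proto, strand = "+",
                               position = 500, n_mismatches = 0)
  )
  cand <- list(protospacer = proto, strand = "+", seq_name = "chrS",
               protospacer_start = 500)
  mm <- count_offtargets(cand, ref1)
  expect_equal(unname(mm), c(0, 0, 0, 0))

  # one extra exact copy elsewhere -> MM0 = 1
  ref2 <- make_reference(
    2000, 0.3, seed = 102,
    planted_sites = data.frame(protospacer = proto, strand = c("+", "+"),
                               position = c(500, 1500),
                               n_mismatches = c(0, 0))
  )
  mm2 <- count_offtargets(cand, ref2)
  expect_equal(unname(mm2)[1], 1)

  # a reverse-strand copy with 2 mismatches -> MM2 = 1
  ref3 <- make_reference(
    2000, 0.3, seed = 103,
    planted_sites = data.frame(protospacer = proto, strand = c("+", "-"),
                               position = c(500, 1500),
                               n_mismatches = c(0, 2))
  )
  mm3 <- count_offtargets(cand, ref3)
  expect_equal(unname(mm3)[3], 1)

  # full agreement with the brute-force window oracle
  for (ref in list(ref1, ref2, ref3)) {
    expect_equal(
      unname(count_offtargets(cand, ref)),
      oracle_offtargets(proto, ref, exclude = cand)
    )
  }
})

test_that("off-target counting matches brute force on a random genome", {
  ref <- make_reference(6000, 0.5, seed = 77)
  cand <- enumerate_candidates(ref)
  set.seed(4)
  for (i in sample.int(nrow(cand), 5)) {
    expect_equal(
      unname(count_offtargets(cand[i, ], ref)),
      oracle_offtargets(cand$protospacer[i], ref, exclude = cand[i, ])
    )
  }
})

test_that("efficiency surrogate evaluates its stated terms and stays in [0,1]", {
  expect_equal(efficiency_score("AAAAAAAAAAAAAAAAAAAA"), 0.15)
  expect_equal(efficiency_score("CCCGTACGTAAGCATCAGTG"), 0.80)
  set.seed(8)
  for (i in 1:50) {
    p <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    e <- efficiency_score(p)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("criteria filter applies the four design rules", {
  m <- function(gc, sc, mmsum, eff) {
    data.frame(gc_percent = gc, self_complementarity = sc,
               mm0 = mmsum, mm1 = 0, mm2 = 0, mm3 = 0, efficiency = eff)
  }
  expect_true(passes_criteria(m(45, 0, 7, 0.69)))
  expect_false(passes_criteria(m(25, 0, 0, 0.9)))   # GC below 30
  expect_false(passes_criteria(m(50, 0, 10, 0.9)))  # off-targets: strict < 10
  expect_false(passes_criteria(m(50, 1, 0, 0.9)))   # self-complementarity != 0
  expect_false(passes_criteria(m(50, 0, 0, 0.19)))  # efficiency below 0.2
  expect_true(passes_criteria(m(30, 0, 9, 0.2)))    # all boundaries inclusive
})
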