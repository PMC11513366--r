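#' Enumerate SpCas9 guide candidates in a region
#'
#' Scans both strands of a region for 23-mer windows ending in an NGG PAM
#' (on the targeted strand) and returns each as a candidate: the 20-nt
#' protospacer written 5'->3' on the targeted strand, the PAM, the strand,
#' the 0-based plus-strand start of the protospacer footprint, and the
#' blunt-cut coordinate (3 bp 5' of the PAM, between protospacer bases
#' 17 and 18). Windows containing `N` are skipped.
#'
#' @param ref Reference sequence (`DNAStringSet`, `DNAString`, or character).
#' @param region A [gregion()] within the reference; `NULL` scans the whole
#'   sequence.
#' @return A `data.frame` with columns `seq_name`, `protospacer`, `pam`,
#'   `strand`, `protospacer_start`, `cut_pos`, sorted by `cut_pos`
#'   (ties: `+` before `-`).
#' @examples
#' enumerate_candidates("AAAAAAAAAAAAAAAAAAAAAGG")
#' @export
enumerate_candidates <- function(ref, region = NULL) {
  s <- seq_as_character(ref)
  nm <- seq_name_of(s)
  if (is.null(region)) region <- gregion(nm, 0, nchar(s))
  if (region$end > nchar(s) || region$start < 0) {
    stop("region lies outside the reference sequence")
  }
  sub <- substr(s, region$start + 1, region$end)
  L <- nchar(sub)
  if (L < 23) stop("region too short to hold a 23-mer guide window")
  ch <- strsplit(sub, "", fixed = TRUE)[[1]]
  cn <- c(0L, cumsum(ch == "N"))
  p <- seq_len(L - 22)              # 1-based window starts within region
  clean <- (cn[p + 23L] - cn[p]) == 0L

  plus <- p[clean & ch[p + 21L] == "G" & ch[p + 22L] == "G"]
  minus <- p[clean & ch[p] == "C" & ch[p + 1L] == "C"]

  g0 <- region$start  # genomic offset
  cand_plus <- if (length(plus)) {
    data.frame(
      seq_name = nm,
      protospacer = substring(sub, plus, plus + 19L),
      pam = substring(sub, plus + 20L, plus + 22L),
      strand = "+",
      protospacer_start = g0 + plus - 1L,
      cut_pos = g0 + plus - 1L + 17L,
      stringsAsFactors = FALSE
    )
  }
  cand_minus <- if (length(minus)) {
    data.frame(
      seq_name = nm,
      protospacer = dna_revcomp(substring(sub, minus + 3L, minus + 22L)),
      pam = dna_revcomp(substring(sub, minus, minus + 2L)),
      strand = "-",
      protospacer_start = g0 + minus - 1L + 3L,
      cut_pos = g0 + minus - 1L + 6L,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(cand_plus, cand_minus)
  if (is.null(out)) {
    out <- data.frame(
      seq_name = character(), protospacer = character(), pam = character(),
      strand = character(), protospacer_start = numeric(),
      cut_pos = numeric(), stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$cut_pos, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

#' Guide GC content
#'
#' @param protospacer Character vector of 20-nt protospacers (ACGT only).
#' @return Percentage(s) in \[0, 100\]: `100 * (#G + #C) / 20`.
#' @examples
#' gc_percent("GTATCAATGTTCTTCCTGGG")  # 45
#' @export
gc_percent <- function(protospacer) {
  check_protospacer(protospacer)
  vapply(protospacer, function(p) {
    100 * sum(charToRaw(p) %in% charToRaw("GC")) / 20
  }, numeric(1), USE.NAMES = FALSE)
}

check_protospacer <- function(protospacer) {
  stopifnot(is.character(protospacer), length(protospacer) >= 1)
  if (any(nchar(protospacer) != 20)) {
    stop("protospacer must be exactly 20 nt")
  }
  if (!all(grepl("^[ACGT]+$", protospacer))) {
    stop("protospacer must contain only A/C/G/T")
  }
  invisible(TRUE)
}

#' Hairpin self-complementarity score
#'
#' Counts potential intramolecular hairpin seeds plus folds against the
#' constant scaffold ("backbone") sequence: (a) ordered position pairs
#' (i, j) with j >= i + 7 where the 4-mer at j equals the reverse
#' complement of the 4-mer at i (a 4-bp stem with a loop of at least 3 nt),
#' and (b) protospacer 4-mers whose reverse complement occurs anywhere in
#' the backbone. Guides used for enrichment should score 0.
#'
#' @param protospacer 20-nt protospacer(s).
#' @param backbone Scaffold sequence folded against; `""` restricts the
#'   score to intramolecular pairs.
#' @return Non-negative integer score(s).
#' @examples
#' self_complementarity("CCCGTACGTAAGCATCAGTG")  # 0
#' @export
self_complementarity <- function(protospacer, backbone = "AGGCTAGTCCGT") {
  check_protospacer(protospacer)
  stopifnot(is.character(backbone), length(backbone) == 1)
  vapply(protospacer, function(p) {
    kmers <- substring(p, 1:17, 4:20)
    rc <- dna_revcomp(kmers)
    intra <- 0L
    for (i in 1:10) {                 # j >= i + 7 and j <= 17
      intra <- intra + sum(kmers[(i + 7L):17L] == rc[i])
    }
    inter <- if (nzchar(backbone)) {
      sum(vapply(rc, function(k) grepl(k, backbone, fixed = TRUE), logical(1)))
    } else 0L
    as.integer(intra + inter)
  }, integer(1), USE.NAMES = FALSE)
}

#' Count mismatch-stratified off-target sites
#'
#' Counts genomic sites (both strands, all records) whose 20-mer differs
#' from the candidate's protospacer at exactly m positions (m = 0..`max_mm`)
#' and is immediately followed, in targeted-strand orientation, by an NGG
#' PAM. The on-target site itself (same record, strand and footprint start)
#' is excluded, matching the convention that a unique guide shows MM0 = 0.
#'
#' @param candidate A one-row candidate `data.frame` (or list) with fields
#'   `protospacer`, and optionally `seq_name`, `strand`, `protospacer_start`
#'   identifying the on-target site to exclude.
#' @param genome Search space: `DNAStringSet` or (named) character vector.
#' @param max_mm Maximum mismatch stratum (default 3; must be <= 20).
#' @return Integer vector `c(mm0, ..., mm<max_mm>)`.
#' @export
count_offtargets <- function(candidate, genome, max_mm = 3) {
  if (max_mm > 20) stop("max_mm cannot exceed the protospacer length (20)")
  proto <- candidate$protospacer
  check_protospacer(proto)
  gen <- as_genome_chars(genome)
  pat <- Biostrings::DNAString(proto)
  counts <- integer(max_mm + 1)
  for (i in seq_along(gen)) {
    L <- nchar(gen[[i]])
    for (ori in c("+", "-")) {
      subj <- if (ori == "+") gen[[i]] else dna_revcomp(gen[[i]])
      hits <- Biostrings::matchPattern(
        pat, Biostrings::DNAString(subj),
        max.mismatch = max_mm, with.indels = FALSE
      )
      for (s1 in BiocGenerics::start(hits)) {
        if (s1 < 1 || s1 + 22 > nchar(subj)) next   # needs room for the PAM
        if (substr(subj, s1 + 21, s1 + 22) != "GG") next
        mm <- str_mismatches(substr(subj, s1, s1 + 19), proto)
        if (mm > max_mm) next
        foot0 <- if (ori == "+") s1 - 1 else L - s1 - 19
        if (identical(ori, candidate$strand %||% NULL) &&
            identical(names(gen)[i], candidate$seq_name %||% NULL) &&
            isTRUE(foot0 == candidate$protospacer_start)) {
          next  # the on-target site
        }
        counts[mm + 1] <- counts[mm + 1] + 1L
      }
    }
  }
  setNames(counts, paste0("mm", 0:max_mm))
}

#' Surrogate cut-efficiency score
#'
#' A fully specified, deterministic stand-in for published on-target
#' activity models, so that designs are reproducible: starting from 0.5 it
#' rewards a PAM-proximal G (+0.2), penalises a PAM-proximal T (-0.1),
#' rewards GC in \[40, 70\] (+0.1), penalises GC outside \[30, 80\] (-0.2),
#' a homopolymer run of >= 5 (-0.15), and nonzero self-complementarity
#' (-0.1), clamped to \[0, 1\]. The scorer is an ordinary function and can
#' be swapped for a published model wherever an `efficiency` column is
#' consumed.
#'
#' @param protospacer 20-nt protospacer(s).
#' @param self_comp Precomputed [self_complementarity()] value(s); computed
#'   if `NULL`.
#' @param backbone Passed to [self_complementarity()] when computing.
#' @return Score(s) in \[0, 1\].
#' @examples
#' efficiency_score("CCCGTACGTAAGCATCAGTG")  # 0.8
#' @export
efficiency_score <- function(protospacer, self_comp = NULL,
                             backbone = "AGGCTAGTCCGT") {
  check_protospacer(protospacer)
  if (is.null(self_comp)) {
    self_comp <- self_complementarity(protospacer, backbone)
  }
  gc <- gc_percent(protospacer)
  base20 <- substr(protospacer, 20, 20)
  maxrun <- vapply(strsplit(protospacer, "", fixed = TRUE), function(ch) {
    max(rle(ch)$lengths)
  }, integer(1))
  eff <- 0.5 +
    0.2 * (base20 == "G") -
    0.1 * (base20 == "T") +
    0.1 * (gc >= 40 & gc <= 70) -
    0.2 * (gc < 30 | gc > 80) -
    0.15 * (maxrun >= 5) -
    0.1 * (self_comp > 0)
  pmin(1, pmax(0, eff))
}

#' Guide-selection criteria
#'
#' Defaults are the enrichment-design rules used throughout the package:
#' GC content between 30 and 80 percent, self-complementarity equal to 0,
#' a total off-target count (MM0-MM3) strictly below 10, and efficiency of
#' at least 0.2.
#'
#' @param gc_min,gc_max GC bounds in percent (inclusive).
#' @param max_self_complementarity Maximum allowed score (default 0).
#' @param max_offtargets Strict upper bound on `mm0+mm1+mm2+mm3`.
#' @param min_efficiency Minimum efficiency (inclusive).
#' @return A `criteria_config` list.
#' @export
criteria_config <- function(gc_min = 30, gc_max = 80,
                            max_self_complementarity = 0,
                            max_offtargets = 10, min_efficiency = 0.2) {
  structure(
    list(
      gc_min = gc_min, gc_max = gc_max,
      max_self_complementarity = max_self_complementarity,
      max_offtargets = max_offtargets, min_efficiency = min_efficiency
    ),
    class = "criteria_config"
  )
}

#' Test guides against the selection criteria
#'
#' @param metrics A `data.frame` with columns `gc_percent`,
#'   `self_complementarity`, `mm0`..`mm3`, `efficiency`.
#' @param criteria A [criteria_config()].
#' @return Logical vector, one element per row.
#' @export
passes_criteria <- function(metrics, criteria = criteria_config()) {
  stopifnot(inherits(criteria, "criteria_config"))
  mm_sum <- metrics$mm0 + metrics$mm1 + metrics$mm2 + metrics$mm3
  metrics$gc_percent >= criteria$gc_min &
    metrics$gc_percent <= criteria$gc_max &
    metrics$self_complementarity <= criteria$max_self_complementarity &
    mm_sum < criteria$max_offtargets &
    metrics$efficiency >= criteria$min_efficiency
}

#' Attach per-guide metrics to a candidate table
#'
#' Adds `gc_percent`, `self_complementarity`, `efficiency` and (optionally)
#' the `mm0`..`mm3` off-target columns to the output of
#' [enumerate_candidates()]. Off-target counting is the expensive step; the
#' tiling designer computes it lazily, so `offtargets = FALSE` leaves the
#' columns as `NA`.
#'
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param genome Off-target search space (required when `offtargets = TRUE`).
#' @param offtargets Whether to count off-targets now.
#' @param backbone Scaffold for [self_complementarity()].
#' @return The candidate table with metric columns appended.
#' @export
add_guide_metrics <- function(candidates, genome = NULL, offtargets = TRUE,
                              backbone = "AGGCTAGTCCGT") {
  n <- nrow(candidates)
  candidates$gc_percent <- if (n) gc_percent(candidates$protospacer) else numeric(0)
  candidates$self_complementarity <-
    if (n) self_complementarity(candidates$protospacer, backbone) else integer(0)
  candidates$efficiency <- if (n) {
    efficiency_score(candidates$protospacer, candidates$self_complementarity)
  } else numeric(0)
  for (col in paste0("mm", 0:3)) candidates[[col]] <- rep(NA_integer_, n)
  if (offtargets && n) {
    if (is.null(genome)) stop("genome required to count off-targets")
    for (i in seq_len(n)) {
      mm <- count_offtargets(candidates[i, ], genome)
      candidates[i, paste0("mm", 0:3)] <- as.list(mm)
    }
  }
  candidates
}
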