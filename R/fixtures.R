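#' Generate a seeded synthetic reference sequence
#'
#' Bases are drawn i.i.d. at the requested GC fraction; optional 23-mer
#' guide sites (protospacer + exact NGG PAM) are then written at stated
#' positions and strands, with a chosen number of protospacer mismatches —
#' the planted-site mechanism used to exercise off-target counting.
#' Deterministic under `seed`.
#'
#' @param length Sequence length in bp (minimum 1000).
#' @param gc_fraction GC content in (0, 1); default 0.4, a PAM density at
#'   which a 31 kb tiling design always finds its guides.
#' @param seed Integer seed.
#' @param planted_sites Optional `data.frame` with columns `protospacer`,
#'   `strand` (`+`/`-`), `position` (0-based plus-strand start of the
#'   23-mer window), `n_mismatches`. Sites must not overlap.
#' @param name Sequence name (default `"chrS"`).
#' @return A single-record, named [Biostrings::DNAStringSet].
#' @export
make_reference <- function(length, gc_fraction = 0.4, seed = 1,
                           planted_sites = NULL, name = "chrS") {
  stopifnot(length >= 1000, gc_fraction > 0, gc_fraction < 1)
  with_seed(seed, {
    bases <- sample(
      c("A", "C", "G", "T"), length, replace = TRUE,
      prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    )
    if (!is.null(planted_sites) && nrow(planted_sites)) {
      ps <- planted_sites[order(planted_sites$position), ]
      if (any(ps$position < 0 | ps$position + 23 > length)) {
        stop("planted site outside the sequence")
      }
      if (nrow(ps) > 1 && any(diff(ps$position) < 23)) {
        stop("planted sites overlap")
      }
      for (i in seq_len(nrow(ps))) {
        proto <- ps$protospacer[i]
        check_protospacer(proto)
        n_mm <- ps$n_mismatches[i] %||% 0
        site <- plant_site_string(proto, n_mm)
        if (ps$strand[i] == "-") site <- dna_revcomp(site)
        bases[(ps$position[i] + 1):(ps$position[i] + 23)] <-
          strsplit(site, "", fixed = TRUE)[[1]]
      }
    }
    Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""), name))
  })
}

# build one planted 23-mer: protospacer with n_mm seeded substitutions,
# followed by an exact NGG PAM (random N)
plant_site_string <- function(proto, n_mm) {
  if (n_mm > 0) {
    ch <- strsplit(proto, "", fixed = TRUE)[[1]]
    at <- sample.int(20, n_mm)
    for (p in at) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    proto <- paste(ch, collapse = "")
  }
  paste0(proto, sample(c("A", "C", "G", "T"), 1), "GG")
}

#' Generate a synthetic multi-exon transcript model
#'
#' Emulates the structure of a ~21 kb retinal gene locus: by default 14
#' exons separated by ~1.4 kb introns, a short 5' UTR in the first exon
#' and a longer 3' UTR in the last, centred in the analysed region with
#' 5 kb clear on each side.
#'
#' @param region The analysed [gregion()] the transcript must fit in.
#' @param strand Transcription strand (default `"+"`).
#' @param exon_lengths Exon lengths in transcription order.
#' @param intron_lengths Intron lengths (one fewer than exons).
#' @param utr5_len,utr3_len UTR lengths (in transcription order) carved
#'   out of the first/last exon.
#' @param offset Genomic offset of the transcript start from
#'   `region$start` (default 5000, mirroring the designed flanks).
#' @param name Transcript name.
#' @return A [transcript_model()].
#' @export
make_transcript <- function(region, strand = "+",
                            exon_lengths = c(300, rep(140, 12), 1000),
                            intron_lengths = rep(1396, 13),
                            utr5_len = 100, utr3_len = 600,
                            offset = 5000, name = "TX1") {
  stopifnot(inherits(region, "gregion"),
            length(intron_lengths) == length(exon_lengths) - 1)
  n <- length(exon_lengths)
  starts <- region$start + offset +
    cumsum(c(0, exon_lengths[-n] + intron_lengths))
  ends <- starts + exon_lengths
  if (ends[n] > region$end) {
    stop("transcript layout does not fit in the region")
  }
  exons <- lapply(seq_len(n), function(i) {
    gregion(region$seq_name, starts[i], ends[i], label = paste0("exon", i))
  })
  stopifnot(utr5_len < exon_lengths[1], utr3_len < exon_lengths[n])
  cds <- if (strand == "+") {
    gregion(region$seq_name, starts[1] + utr5_len, ends[n] - utr3_len)
  } else {
    gregion(region$seq_name, starts[1] + utr3_len, ends[n] - utr5_len)
  }
  transcript_model(region, strand, exons, cds, name = name)
}

#' Generate a pair of synthetic variant callsets
#'
#' Builds two callsets with a configured overlap over a region, emulating
#' a long-read/short-read comparison: callset A holds
#' `n_shared + n_only_a` variants placed in chosen genic categories;
#' callset B holds `n_shared` of A's variants plus `n_total_b - n_shared`
#' of its own. `n_rare` of A's variants get an allele frequency below
#' 0.001; A-only variants get low qualities (4-10), mimicking
#' low-coverage false positives. Deterministic under `seed`.
#'
#' @param region The analysed [gregion()].
#' @param transcript A [transcript_model()] placing the categories.
#' @param n_total_b,n_shared,n_only_a Callset sizes (defaults 69 / 68 / 3).
#' @param category_counts Named counts for A's variants over
#'   `coding` / `intronic` / `utr3` / `utr5` / `flanking`; must sum to
#'   `n_shared + n_only_a`. Default `c(coding = 9, intronic = 59, utr3 = 3)`.
#' @param n_rare How many of A's variants are rare (AF < 0.001); default 7.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the callsets are also
#'   written as `callset_a.vcf` / `callset_b.vcf`.
#' @return List with variant tables `a` and `b` (and `path_a` / `path_b`
#'   when written).
#' @export
make_callsets <- function(region, transcript,
                          n_total_b = 69, n_shared = 68, n_only_a = 3,
                          category_counts = c(coding = 9, intronic = 59,
                                              utr3 = 3),
                          n_rare = 7, seed = 1, dir = NULL) {
  stopifnot(n_shared <= n_total_b, n_shared >= 0, n_only_a >= 0)
  n_a <- n_shared + n_only_a
  if (sum(category_counts) != n_a) {
    stop("category_counts must sum to n_shared + n_only_a (", n_a, ")")
  }
  pools <- category_base_pools(region, transcript)
  with_seed(seed, {
    pos0 <- unlist(lapply(names(category_counts), function(cat) {
      pool <- pools[[cat]]
      k <- category_counts[[cat]]
      if (length(pool) < k) {
        stop("region too small for ", k, " ", cat, " variants")
      }
      sample(pool, k)
    }))
    a <- data.frame(
      seq_name = region$seq_name,
      pos = sort(pos0) + 1,
      ref = sample(c("A", "C", "G", "T"), n_a, replace = TRUE),
      alt = NA_character_,
      qual = round(runif(n_a, 20, 60), 1),
      allele_frequency = round(runif(n_a, 0.0011, 0.5), 6),
      stringsAsFactors = FALSE
    )
    a$alt <- vapply(a$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)
    rare_idx <- sample.int(n_a, min(n_rare, n_a))
    a$allele_frequency[rare_idx] <- round(runif(length(rare_idx), 1e-5, 9e-4), 6)
    shared_idx <- sort(sample.int(n_a, n_shared))
    only_a_idx <- setdiff(seq_len(n_a), shared_idx)
    a$qual[only_a_idx] <- round(runif(length(only_a_idx), 4, 10), 1)

    n_only_b <- n_total_b - n_shared
    b_extra <- if (n_only_b > 0) {
      free <- setdiff(seq(region$start, region$end - 1), sort(pos0))
      ep <- sample(free, n_only_b)
      er <- sample(c("A", "C", "G", "T"), n_only_b, replace = TRUE)
      data.frame(
        seq_name = region$seq_name,
        pos = ep + 1,
        ref = er,
        alt = vapply(er, function(r) {
          sample(setdiff(c("A", "C", "G", "T"), r), 1)
        }, character(1), USE.NAMES = FALSE),
        qual = round(runif(n_only_b, 20, 60), 1),
        allele_frequency = round(runif(n_only_b, 0.0011, 0.5), 6),
        stringsAsFactors = FALSE
      )
    }
    b <- rbind(a[shared_idx, ], b_extra)
    b <- b[order(b$pos), ]
    rownames(a) <- rownames(b) <- NULL
    out <- list(a = a, b = b)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$path_a <- write_variant_table(a, file.path(dir, "callset_a.vcf"))
      out$path_b <- write_variant_table(b, file.path(dir, "callset_b.vcf"))
    }
    out
  })
}

# 0-based base pools per genic category, derived from the transcript model
category_base_pools <- function(region, transcript) {
  ex_start <- vapply(transcript$exons, function(e) e$start, numeric(1))
  ex_end <- vapply(transcript$exons, function(e) e$end, numeric(1))
  all_pos <- seq(region$start, region$end - 1)
  exonic <- unlist(mapply(seq, ex_start, ex_end - 1, SIMPLIFY = FALSE))
  cds <- seq(transcript$cds$start, transcript$cds$end - 1)
  span <- seq(ex_start[1], ex_end[length(ex_end)] - 1)
  utr_lo <- exonic[exonic < transcript$cds$start]
  utr_hi <- exonic[exonic >= transcript$cds$end]
  list(
    coding = intersect(exonic, cds),
    utr5 = if (transcript$strand == "+") utr_lo else utr_hi,
    utr3 = if (transcript$strand == "+") utr_hi else utr_lo,
    intronic = setdiff(span, exonic),
    flanking = setdiff(all_pos, span)
  )
}
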