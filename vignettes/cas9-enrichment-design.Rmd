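---
title: "Designing and evaluating Cas9-targeted nanopore enrichment panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating Cas9-targeted nanopore enrichment panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas9tiler)
```

## The problem

Amplification-free targeted nanopore sequencing excises a locus of interest
directly from genomic DNA with CRISPR-Cas9 ribonucleoprotein complexes:
after global dephosphorylation, only the fresh cut ends can be dA-tailed
and ligated to sequencing adapters, so reads start at cut sites and run
into the excised region. For loci larger than ~20 kb a single guide pair is
not enough; a *tiling* panel of several opposite-strand guide pairs, cut
sites spaced less than 10 kb apart, is needed to cover the region evenly.
`cas9tiler` implements the full desk-side workflow around such a panel:
guide discovery and scoring, tile-wise pair selection, reagent pooling, a
generative read simulator, coverage QC, and variant-callset comparison. A
motivating use case is the ~21 kb *RPE65* locus (retinal dystrophy
diagnostics), designed with 5 kb flanks as a 31,133 bp target.

## Coordinate model

Internally everything is 0-based and half-open (the BED convention);
genome-browser region strings such as `"chr1:68,423,822-68,454,954"`
(1-based inclusive) and VCF positions are converted at the boundary by
`parse_region_string()` and `read_variant_table()`. This keeps interval
arithmetic free of off-by-one ambiguity: the string above has length
`end − start + 1 = 31,133` and parses to `start = 68,423,821`,
`end = 68,454,954`.

## Guide discovery and scoring

`enumerate_candidates()` scans both strands for 23-mer windows whose
targeted-strand sequence ends in an NGG PAM. Each candidate records its
20-nt protospacer, PAM, strand, plus-strand footprint start, and the blunt
cut coordinate 3 bp 5′ of the PAM (between protospacer bases 17 and 18,
standard SpCas9 biochemistry). Windows containing `N` are discarded rather
than expanded.

Per-guide metrics mirror a standard guide-design report:

* **GC content** — `100 × (#G + #C) / 20`.
* **Self-complementarity** — a hairpin heuristic counting 4-bp seeds:
  ordered protospacer position pairs `(i, j)` with `j ≥ i + 7` whose
  4-mers are reverse complements (a 4-bp stem with a ≥3-nt loop), plus
  protospacer 4-mers whose reverse complement occurs in the constant
  scaffold (`"AGGCTAGTCCGT"` by default). Usable guides score 0.
* **Off-target counts MM0–MM3** — `count_offtargets()` counts genomic
  sites (both strands, all records) at each exact mismatch level whose
  20-mer is followed by an NGG PAM, excluding the on-target site itself.
  The search uses `Biostrings::matchPattern()` with mismatches; the test
  suite cross-checks it against an independent sliding-window scan.
* **Efficiency** — published on-target activity models are proprietary to
  their tools and version-dependent, so the package ships a fully
  specified deterministic surrogate (`efficiency_score()`): 0.5, +0.2 for
  a PAM-proximal G, −0.1 for a PAM-proximal T, +0.1 for GC in [40, 70],
  −0.2 for GC outside [30, 80], −0.15 for a homopolymer run ≥ 5, −0.1 for
  nonzero self-complementarity, clamped to [0, 1]. It rewards and
  penalises the features those models agree on while staying reproducible;
  any scorer producing an `efficiency` column can be substituted.

`passes_criteria()` applies the selection rules used for enrichment
panels: GC between 30 and 80%, self-complementarity 0, total off-target
count below 10, efficiency at least 0.2 (all boundaries as stated).

## Tiling design

`design_tiling()` proceeds in three deterministic steps:

1. **Flanks** — the locus is widened by 5 kb per side
   (`expand_with_flanks()`), because coverage decays toward cut sites and
   the outermost cuts should sit outside the region of interest.
2. **Tiles** — the region is partitioned into
   `n = ceiling(length / 10 kb)` contiguous near-equal blocks
   (`build_tiles()`); boundary `k` sits at
   `start + round_half_up(k · length / n)`.
3. **Pair selection** — for each tile, the minus-strand guide cutting near
   the tile's left edge and the plus-strand guide cutting near its right
   edge are chosen (`select_pair_for_tile()`), so both reads run into the
   tile. Within a growing window around the edge (±1.5 kb, stepped by
   0.5 kb up to ±5 kb) the highest-efficiency criteria-passing candidate
   wins; ties break by distance to the edge, then lexicographically by
   protospacer, so the procedure is fully reproducible.

Two constraints beyond the per-edge rule are enforced because the design
invariants require them and independent per-edge choices cannot guarantee
them: a pair's plus cut must lie within one block size downstream of its
minus cut, and each tile's minus cut must lie beyond the previous tile's
plus cut. The second keeps cut sites strictly interleaved
(−, +, −, +, …) along the region; without it two near-boundary cuts can
face each other a few hundred bases apart, and the tiny fragment between
them truncates both guides' reads. Off-target counting, the expensive
metric, is evaluated lazily only for candidates actually inspected during
selection (with caching); the result is identical to eager scoring.

Designing on a reference and on its reverse complement yields mirrored
candidate sets exactly; whole designs mirror only up to 1 bp because
round-half-up tile boundaries are not perfectly symmetric (offset 15,566.5
rounds to 15,567 from either end of a 31,133 bp region).

`assign_pools()` arranges guides for library preparation: the
**bricklayer** layout puts odd-numbered pairs in pool A and even-numbered
pairs in pool B, so neighbouring pairs never share a pool; the **highway**
layout pools by cut direction (minus-strand guides in C, plus-strand in
D). Pools always partition the panel.

```{r design-example, eval = FALSE}
ref <- make_reference(31133, gc_fraction = 0.4, seed = 42)
design <- design_tiling(ref, gregion("chrS", 0, 31133), flank = 0)
design_report(design, list(assign_pools(design, "bricklayer"),
                           assign_pools(design, "highway")))
```

## The read simulator

`simulate_reads()` abstracts the enrichment chemistry into a generative
model: per molecule, each guide cuts with probability equal to its
efficiency score (the score doubles as a capture probability — a modelling
choice, not a calibrated rate); each realised cut releases one read
starting at the cut and running in the guide's direction (minus-strand
guides read toward increasing coordinates, plus-strand toward decreasing,
matching the pair geometry above). Read length is the minimum of a
lognormal draw (median `exp(log 8000)` = 8 kb, log-sd 0.6 by default —
the read-size scale of MinION enrichment runs), the distance to the next
realised cut on the molecule (every cut fragments it), and the sequence
end. Background (non-cut) reads start uniformly at a default rate of 0.01
per molecule. Per-read mean quality is Normal(12, 2.5) truncated at 0,
and `apply_qscore_filter()` retains reads at or above Qscore 9
(inclusive), the PASS convention of the targeted runs this emulates.

`emit_fastq()` writes reads with substitution errors at the Phred rate
implied by each read's quality; `emit_truth_alignments()` writes the
ground-truth intervals as strict BED6 (name = origin, score = mean
quality, strand = read direction) so they round-trip through any BED
reader as well as `read_truth_alignments()`.

Two geometric consequences are worth knowing. First, each cut's read pile
decays monotonically away from the cut — the sawtooth coverage pattern
characteristic of Cas9 enrichment; the aggregate profile over an
opposite-strand pair is *not* monotone, since the partner's reads pile up
from the other side. Second, read lengths are capped by the pair span: on
a 31,133 bp region equal tiling gives ~7.8 kb spans and the median read
length sits near that cap, while 10 kb tiles (pair spans ~9–10 kb, the
spacing tiling protocols aim for) leave the 8 kb lognormal median
unchanged. Simulator checks of the 8 kb median therefore run on a
40,000 bp reference with four exact 10 kb tiles; problem sizes throughout
the tests (1000 molecules, ≤ 40 kb references) keep every check in
seconds while leaving ≥ 500 reads for distributional assertions.

## Coverage QC

`depth_profile()` computes exact per-base depth over a region (via
`IRanges::coverage()`, verified against brute-force membership counting),
`depth_stats()` reports min/mean/max (mean rounded half-up to 2 decimals),
`cumulative_coverage()` the percentage of bases at or above each depth
threshold, and `read_n50()` the standard length-weighted N50 (largest L
such that reads ≥ L hold at least half of all bases). A read belongs to a
region if it overlaps it by at least 1 bp. `qc_summary()` bundles these
into the run-level statistics a targeted experiment reports.

## Variant comparison

`match_variants()` compares a test callset against a reference callset on
the exact key `(chrom, pos, ref, alt)`; concordance is the percentage of
the reference set recovered, rounded half-up to 2 decimals. No indel
re-normalisation (left-alignment) is attempted — representation-sensitive
matching is a documented limitation, consistent with the observation that
duplication-type indels are where exact-key comparisons disagree.

`classify_variant()` places each variant in exactly one category against a
transcript model: `coding` (exonic within the CDS), `utr5`/`utr3` (exonic
outside the CDS, side resolved by strand), `intronic` (inside the
transcript span, with distance to the nearest exonic base carried so any
"deep intronic" cutoff can be applied downstream — the package does not
fix one), or `flanking`. `summarize_variants()` adds per-category
percentages and two triage tallies: variants rarer than 0.001 allele
frequency (strictly; missing frequency counts as rare, the standard
rare-disease reading of "absent from population databases") and variants
below quality 10, the range in which enrichment-only calls tend to be
false positives. `frequency_filter()` applies the same rarity rule as a
filter.

## Synthetic fixtures

All tests and the acceptance script run on generated data.
`make_reference()` draws i.i.d. bases at a requested GC fraction and can
plant 23-mer guide sites with an exact number of protospacer mismatches —
the ground truth for off-target recovery checks. The default GC of 0.4
makes NGG PAMs dense enough (~8% of positions per strand) that a 31 kb
design always finds its guides. `make_transcript()` lays out a 14-exon
gene (~3 kb of exon in ~21 kb of span, short 5′ UTR, longer 3′ UTR)
echoing the structure of a compact retinal-disease locus, centred with
5 kb clear on each side. `make_callsets()` builds two callsets with a
configured overlap (by default 69 reference-set variants of which 68 are
shared, plus 3 test-only variants with low qualities) and a configured
category mix (9 coding / 59 intronic / 3 UTR3 of 71), with 7 variants
below the rarity threshold. Everything is a pure function of its seed.

What the synthetic data does *not* emulate: real human sequence
composition (repeats, segmental duplications — off-target landscapes are
i.i.d.-random or explicitly planted), basecalling error structure
(homopolymer errors, indels — the simulator injects substitutions only),
alignment ambiguity, and real variant spectra. Passing tests demonstrate
the correctness of the computations, not the clinical performance of the
wet-lab protocol.

## Numerical conventions and edge cases

* Percentages and means print rounded half away from zero to 2 decimals
  (so 9/71 → 12.68, 59/71 → 83.10), with a small epsilon guarding against
  floating-point representation of quotients.
* Ties in pair selection are broken deterministically (efficiency, then
  edge distance, then protospacer string).
* Zero-width BED intervals, inverted region strings, empty FASTA files,
  sub-1000 bp block sizes and flanks running past the origin are rejected
  with errors rather than silently corrected.
* A design that cannot place a criteria-passing guide within ±5 kb of a
  tile edge fails loudly; it does not relax the criteria.

## Known limitations

* The efficiency surrogate is not a trained activity model; absolute
  efficiency values are not comparable with published tools, only the
  criteria logic around them is.
* Off-target counting is exact-mismatch, NGG-only, bulge-free, and
  practical for references up to a few hundred kb — panel-scale, not
  genome-scale.
* The capture model ignores DNA quality and fragmentation, which dominate
  real yield differences between libraries; relative pool-layout yields
  are therefore out of scope.
* Callset comparison is site-level; genotypes and structural variants are
  not compared.
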