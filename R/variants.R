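#' Transcript model
#'
#' A minimal gene model used to classify variants by genic region: an
#' ordered set of non-overlapping exons, the genomic span of the coding
#' sequence, and the transcription strand.
#'
#' @param region The analysed [gregion()] the model lives in.
#' @param strand `"+"` or `"-"` (transcription direction).
#' @param exons List of [gregion()] exons, non-overlapping, sorted by start.
#' @param cds A [gregion()]: genomic span of the coding sequence, contained
#'   in the exon span.
#' @param name Transcript name.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(region, strand, exons, cds, name = "TX1") {
  stopifnot(inherits(region, "gregion"), strand %in% c("+", "-"),
            length(exons) >= 1, inherits(cds, "gregion"))
  st <- vapply(exons, function(e) e$start, numeric(1))
  en <- vapply(exons, function(e) e$end, numeric(1))
  if (is.unsorted(st, strictly = TRUE) || any(st[-1] < en[-length(en)])) {
    stop("exons must be non-overlapping and sorted by start")
  }
  if (cds$start < st[1] || cds$end > en[length(en)]) {
    stop("cds must lie within the exon span")
  }
  structure(
    list(region = region, strand = strand, exons = exons, cds = cds,
         name = name),
    class = "transcript_model"
  )
}

#' Restrict variants to a region
#'
#' Keeps variants whose 1-based position falls within the region's printed
#' (1-based inclusive) bounds, preserving order.
#'
#' @param variants Variant table ([read_variant_table()]).
#' @param region A [gregion()].
#' @return The filtered variant table.
#' @export
restrict_to_region <- function(variants, region) {
  stopifnot(inherits(region, "gregion"))
  keep <- variants$seq_name == region$seq_name &
    variants$pos >= region$start + 1 & variants$pos <= region$end
  variants[keep, , drop = FALSE]
}

#' Compare two variant callsets
#'
#' Variants match on the exact key `(seq_name, pos, ref, alt)` — no indel
#' re-normalisation is attempted. Callset `b` is the reference set:
#' concordance is the percentage of `b` also found in `a`.
#'
#' @param a,b Variant tables (e.g. test and reference callsets).
#' @return A `callset_comparison` list: `shared` (rows of `b` found in
#'   `a`), `only_a`, `only_b`, `concordance_pct` (2 decimals, half-up),
#'   `n_a`, `n_b`.
#' @export
match_variants <- function(a, b) {
  if (nrow(b) == 0) stop("reference callset (b) is empty")
  key <- function(v) paste(v$seq_name, v$pos, toupper(v$ref), toupper(v$alt),
                           sep = "\r")
  ka <- key(a)
  kb <- key(b)
  structure(
    list(
      shared = b[kb %in% ka, , drop = FALSE],
      only_a = a[!(ka %in% kb), , drop = FALSE],
      only_b = b[!(kb %in% ka), , drop = FALSE],
      concordance_pct = round_half_up(100 * sum(kb %in% ka) / nrow(b), 2),
      n_a = nrow(a), n_b = nrow(b)
    ),
    class = "callset_comparison"
  )
}

#' @export
print.callset_comparison <- function(x, ...) {
  cat(sprintf(
    "<callset_comparison> shared %d | only_a %d | only_b %d | concordance %.2f%% (of %d)\n",
    nrow(x$shared), nrow(x$only_a), nrow(x$only_b), x$concordance_pct, x$n_b
  ))
  invisible(x)
}

#' Classify a variant by genic region
#'
#' Categories partition all in-region variants: `coding` (within an exon
#' and the CDS span), `utr5`/`utr3` (exonic outside the CDS; side resolved
#' by transcript strand), `intronic` (inside the transcript span but not
#' exonic), `flanking` (outside the transcript span). `distance_to_exon`
#' is 0 for exonic variants and the base distance to the nearest exonic
#' base otherwise, so callers can apply any "deep intronic" cutoff.
#'
#' @param v A single variant (one-row `data.frame` or list with `pos`,
#'   1-based).
#' @param model A [transcript_model()].
#' @return List with `category` and `distance_to_exon`.
#' @export
classify_variant <- function(v, model) {
  stopifnot(inherits(model, "transcript_model"))
  pos0 <- v$pos - 1  # 0-based base coordinate
  if (pos0 < model$region$start || pos0 >= model$region$end) {
    stop("variant at position ", v$pos, " lies outside the analysed region")
  }
  ex_start <- vapply(model$exons, function(e) e$start, numeric(1))
  ex_end <- vapply(model$exons, function(e) e$end, numeric(1))
  in_exon <- any(pos0 >= ex_start & pos0 < ex_end)
  if (in_exon) {
    cds <- model$cds
    category <- if (pos0 >= cds$start && pos0 < cds$end) {
      "coding"
    } else if (pos0 < cds$start) {
      if (model$strand == "+") "utr5" else "utr3"
    } else {
      if (model$strand == "+") "utr3" else "utr5"
    }
    return(list(category = category, distance_to_exon = 0))
  }
  # distance to the nearest exonic base
  d <- min(c(
    ifelse(pos0 < ex_start, ex_start - pos0, Inf),
    ifelse(pos0 >= ex_end, pos0 - ex_end + 1, Inf)
  ))
  span <- c(ex_start[1], ex_end[length(ex_end)])
  category <- if (pos0 >= span[1] && pos0 < span[2]) "intronic" else "flanking"
  list(category = category, distance_to_exon = d)
}

#' @rdname classify_variant
#' @param variants A variant table; classified row by row.
#' @return For `classify_variants()`: a `data.frame` with `category` and
#'   `distance_to_exon` columns, one row per variant.
#' @export
classify_variants <- function(variants, model) {
  out <- lapply(seq_len(nrow(variants)), function(i) {
    classify_variant(variants[i, ], model)
  })
  data.frame(
    category = vapply(out, `[[`, character(1), "category"),
    distance_to_exon = vapply(out, `[[`, numeric(1), "distance_to_exon"),
    stringsAsFactors = FALSE
  )
}

#' Summarise a classified callset
#'
#' Per-category counts and percentages (2 decimals, half-up), plus the
#' rarity and quality tallies used when triaging candidate variants:
#' `n_rare` counts variants with `allele_frequency < rare_af` *or* missing
#' (absent from population databases), `n_low_qual` counts variants with
#' `qual < qual_min`.
#'
#' @param classes Classification table from [classify_variants()].
#' @param variants The matching variant table.
#' @param rare_af Strict rarity threshold on allele frequency
#'   (default 0.001).
#' @param qual_min Low-quality threshold (default 10).
#' @return A `variant_summary` list: `table` (category, count, pct),
#'   `n_total`, `n_rare`, `n_low_qual`.
#' @export
summarize_variants <- function(classes, variants, rare_af = 0.001,
                               qual_min = 10) {
  stopifnot(nrow(classes) == nrow(variants))
  n <- nrow(variants)
  counts <- table(factor(classes$category,
                         levels = c("coding", "utr5", "utr3", "intronic",
                                    "flanking")))
  counts <- counts[counts > 0]
  tab <- data.frame(
    category = names(counts),
    count = as.integer(counts),
    pct = round_half_up(100 * as.integer(counts) / n, 2),
    stringsAsFactors = FALSE
  )
  af <- variants$allele_frequency
  structure(
    list(
      table = tab,
      n_total = n,
      n_rare = sum(is.na(af) | af < rare_af),
      n_low_qual = sum(variants$qual < qual_min, na.rm = TRUE)
    ),
    class = "variant_summary"
  )
}

#' Filter variants by population allele frequency
#'
#' Keeps variants rarer than `max_af` (strict) and variants with no
#' frequency annotation (absent from the population databases).
#'
#' @param variants Variant table.
#' @param max_af Strict threshold (default 0.001).
#' @return The filtered table.
#' @export
frequency_filter <- function(variants, max_af = 0.001) {
  af <- variants$allele_frequency
  variants[is.na(af) | af < max_af, , drop = FALSE]
}

#' Write / read a transcript model as a BED-like table
#'
#' One BED6 row per exon (name `exon<i>`) plus one `cds` row giving the
#' coding span; the strand column carries the transcription direction.
#'
#' @param model A [transcript_model()].
#' @param path Output path.
#' @param region Analysed region to attach on read; defaults to the exon
#'   span.
#' @return `path` invisibly; for [read_transcript_table()], a
#'   `transcript_model`.
#' @export
write_transcript_table <- function(model, path) {
  rows <- c(
    vapply(seq_along(model$exons), function(i) {
      e <- model$exons[[i]]
      paste(e$seq_name,
            format(e$start, scientific = FALSE, trim = TRUE),
            format(e$end, scientific = FALSE, trim = TRUE),
            paste0("exon", i), "0", model$strand, sep = "\t")
    }, character(1)),
    paste(model$cds$seq_name,
          format(model$cds$start, scientific = FALSE, trim = TRUE),
          format(model$cds$end, scientific = FALSE, trim = TRUE),
          "cds", "0", model$strand, sep = "\t")
  )
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_transcript_table
#' @export
read_transcript_table <- function(path, region = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("seq_name", "start", "end", "name",
                                  "score", "strand"))
  ex <- tab[grepl("^exon", tab$name), , drop = FALSE]
  cds <- tab[tab$name == "cds", , drop = FALSE]
  if (nrow(ex) == 0 || nrow(cds) != 1) {
    stop("transcript table needs exon rows and exactly one cds row: ", path)
  }
  ex <- ex[order(ex$start), ]
  exons <- lapply(seq_len(nrow(ex)), function(i) {
    gregion(ex$seq_name[i], ex$start[i], ex$end[i], label = ex$name[i])
  })
  if (is.null(region)) {
    region <- gregion(ex$seq_name[1], min(ex$start), max(ex$end))
  }
  transcript_model(region, strand = tab$strand[1], exons = exons,
                   cds = gregion(cds$seq_name, cds$start, cds$end))
}
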