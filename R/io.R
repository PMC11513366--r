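#' Read a (multi-)FASTA file
#'
#' Sequences are uppercased and returned in file order as a
#' [Biostrings::DNAStringSet]. Plain and gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    stop("duplicate record names in FASTA: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  if (!is_dna_string(seqs)) {
    stop("FASTA sequences contain characters outside {A,C,G,T,N}")
  }
  Biostrings::DNAStringSet(setNames(seqs, names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED3/BED4+ file as a list of regions
#'
#' Intervals are kept in file order in the native BED convention
#' (0-based, half-open); column 4, when present, becomes the region label.
#' Empty (zero-width) intervals are rejected.
#'
#' @param path Path to a BED file (plain or gzip).
#' @return A list of [gregion()] objects.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  w <- BiocGenerics::width(gr)
  if (any(w < 1)) {
    stop("BED interval with start >= end at line(s): ",
         paste(which(w < 1), collapse = ", "))
  }
  labels <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$name)
  } else {
    rep(NA_character_, length(gr))
  }
  lapply(seq_along(gr), function(i) {
    gregion(
      as.character(GenomeInfoDb::seqnames(gr))[i],
      BiocGenerics::start(gr)[i] - 1,
      BiocGenerics::end(gr)[i],
      label = if (is.na(labels[i])) NULL else labels[i]
    )
  })
}

#' Write regions to a BED file
#'
#' @param regions A list of [gregion()] (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  df <- as_region_df(regions)
  has_label <- !all(is.na(df$label))
  cols <- data.frame(
    df$seq_name,
    format(df$start, scientific = FALSE, trim = TRUE),
    format(df$end, scientific = FALSE, trim = TRUE)
  )
  if (has_label) cols$name <- ifelse(is.na(df$label), ".", df$label)
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal VCF into a variant table
#'
#' Only the eight fixed VCF columns are used; genotype columns are ignored.
#' `QUAL` of `"."` becomes `NA`; an `AF=` key in INFO populates
#' `allele_frequency`. Positions stay 1-based as in the file.
#'
#' @param path Path to a VCF (plain or bgzip/gzip).
#' @return A `data.frame` with columns `seq_name`, `pos`, `ref`, `alt`,
#'   `qual`, `allele_frequency`, in file order.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (is.null(fx) || ncol(fx) < 8) {
    stop("VCF is missing mandatory columns (need CHROM..INFO): ", path)
  }
  pos <- suppressWarnings(as.numeric(fx[, "POS"]))
  if (anyNA(pos)) stop("non-numeric POS in VCF: ", path)
  if (any(pos < 1)) stop("POS must be >= 1 in VCF: ", path)
  ref <- toupper(as.character(fx[, "REF"]))
  alt <- toupper(as.character(fx[, "ALT"]))
  if (any(is.na(ref) | is.na(alt) | !nzchar(ref) | !nzchar(alt))) {
    stop("REF and ALT must be non-empty: ", path)
  }
  if (any(ref == alt)) stop("REF and ALT must differ: ", path)
  qual <- suppressWarnings(as.numeric(fx[, "QUAL"]))
  info <- as.character(fx[, "INFO"])
  af_m <- regmatches(info, regexec("(?:^|;)AF=([^;]+)", info))
  af <- vapply(af_m, function(m) {
    if (length(m) == 2) suppressWarnings(as.numeric(m[2])) else NA_real_
  }, numeric(1))
  data.frame(
    seq_name = as.character(fx[, "CHROM"]),
    pos = pos,
    ref = ref,
    alt = alt,
    qual = qual,
    allele_frequency = af,
    stringsAsFactors = FALSE
  )
}

#' Write a variant table as a minimal VCF
#'
#' @param variants A variant `data.frame` as returned by
#'   [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  qual <- ifelse(is.na(variants$qual), ".",
                 format(variants$qual, trim = TRUE, scientific = FALSE))
  info <- ifelse(is.na(variants$allele_frequency), ".",
                 sprintf("AF=%.6g", variants$allele_frequency))
  body <- paste(variants$seq_name,
                format(variants$pos, scientific = FALSE, trim = TRUE),
                ".", variants$ref, variants$alt, qual, "PASS", info,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
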