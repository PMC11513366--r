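# Independent brute-force oracles, deliberately written as plain sliding-
# window scans (no Biostrings matching) so they cross-check the package's
# implementations.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# mismatch-stratified off-target counts by scanning every 23-mer window on
# both strands of every record; excludes the on-target (name, strand, start)
oracle_offtargets <- function(proto, genome, max_mm = 3, exclude = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  counts <- integer(max_mm + 1)
  pch <- strsplit(proto, "")[[1]]
  for (nm in names(genome)) {
    s <- genome[[nm]]
    L <- nchar(s)
    for (w in seq_len(L - 22)) {
      win <- substr(s, w, w + 22)
      for (strand in c("+", "-")) {
        site <- if (strand == "+") win else oracle_revcomp(win)
        if (substr(site, 22, 23) != "GG") next
        mm <- sum(strsplit(substr(site, 1, 20), "")[[1]] != pch)
        if (mm > max_mm) next
        foot0 <- if (strand == "+") w - 1 else w + 2
        if (!is.null(exclude) && strand == exclude$strand &&
            nm == exclude$seq_name && foot0 == exclude$protospacer_start) next
        counts[mm + 1] <- counts[mm + 1] + 1L
      }
    }
  }
  counts
}

# per-base depth by explicit membership counting
oracle_depth <- function(starts, ends, region_start, region_end) {
  vapply(seq(region_start, region_end - 1), function(b) {
    sum(starts <= b & b < ends)
  }, numeric(1))
}

# every 23-mer window scan for candidate enumeration cross-checks
oracle_candidates <- function(s) {
  L <- nchar(s)
  out <- list()
  for (w in seq_len(max(L - 22, 0))) {
    win <- substr(s, w, w + 22)
    if (grepl("N", win, fixed = TRUE)) next
    if (substr(win, 22, 23) == "GG") {
      out[[length(out) + 1]] <- list(strand = "+", start = w - 1,
                                     proto = substr(win, 1, 20))
    }
    rc <- oracle_revcomp(win)
    if (substr(rc, 22, 23) == "GG") {
      out[[length(out) + 1]] <- list(strand = "-", start = w + 2,
                                     proto = substr(rc, 1, 20))
    }
  }
  out
}
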