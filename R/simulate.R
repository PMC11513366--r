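#' Simulator configuration
#'
#' Parameters of the generative model of Cas9 cut-site capture and nanopore
#' read production. Defaults emulate the enrichment runs the package
#' targets: read lengths lognormal with median `exp(read_length_log_mean)`
#' = 8 kb, per-read quality Normal(12, 2.5) truncated at 0, and a PASS
#' threshold of Qscore 9.
#'
#' @param n_molecules Number of input DNA molecules (default 1000).
#' @param read_length_log_mean,read_length_log_sd Lognormal read-length
#'   parameters (defaults `log(8000)` and 0.6).
#' @param background_rate Per-molecule probability of one non-cut
#'   (background) read (default 0.01).
#' @param qscore_mean,qscore_sd Per-read mean quality distribution
#'   (defaults 12 and 2.5).
#' @param qscore_min_pass PASS filter threshold, inclusive (default 9).
#' @param seed Integer seed making runs reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_molecules = 1000,
                       read_length_log_mean = log(8000),
                       read_length_log_sd = 0.6,
                       background_rate = 0.01,
                       qscore_mean = 12, qscore_sd = 2.5,
                       qscore_min_pass = 9,
                       seed = 1) {
  stopifnot(
    n_molecules >= 1, read_length_log_sd >= 0,
    background_rate >= 0, background_rate <= 1,
    qscore_sd >= 0
  )
  structure(
    list(
      n_molecules = n_molecules,
      read_length_log_mean = read_length_log_mean,
      read_length_log_sd = read_length_log_sd,
      background_rate = background_rate,
      qscore_mean = qscore_mean, qscore_sd = qscore_sd,
      qscore_min_pass = qscore_min_pass,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate cut-initiated nanopore reads
#'
#' For each molecule, each designed guide cuts with probability equal to
#' its efficiency score. Every realised cut releases one read starting at
#' the cut site: minus-strand guides read toward increasing coordinates,
#' plus-strand guides toward decreasing coordinates, so reads flow into the
#' tile the pair serves. Read length is the minimum of a lognormal draw,
#' the distance to the next realised cut on the same molecule in the read
#' direction (the molecule is fragmented by every cut), and the distance to
#' the sequence end. Background reads start uniformly with probability
#' `background_rate` per molecule and a random direction. Per-read mean
#' quality is Normal truncated at 0. Reruns with the same seed are
#' identical.
#'
#' @param ref Reference sequence the design was made on.
#' @param design A `tiling_design` (or its guide table) with `cut_pos`,
#'   `strand`, `efficiency`, `name` columns.
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `read_id`, `start`, `end` (0-based,
#'   half-open), `direction` (`fwd`/`rev`), `mean_q`, `origin`
#'   (`cut`/`background`), `guide_name`.
#' @export
simulate_reads <- function(ref, design, config = sim_config()) {
  g <- design_guides(design)
  if (is.null(g) || nrow(g) == 0) stop("empty design")
  s <- seq_as_character(ref)
  L <- nchar(s)
  if (any(g$cut_pos < 0 | g$cut_pos > L)) {
    stop("design cut sites fall outside the reference")
  }
  ids <- starts <- ends <- dirs <- qs <- origins <- guides <- vector("list", 0)
  emit <- function(id, st, en, dir, q, origin, guide) {
    k <- length(ids) + 1
    ids[[k]] <<- id; starts[[k]] <<- st; ends[[k]] <<- en
    dirs[[k]] <<- dir; qs[[k]] <<- q; origins[[k]] <<- origin
    guides[[k]] <<- guide
  }
  clipped_read <- function(cp, dir, cuts, len) {
    # available span from cut/start position to the next fragmentation point
    if (dir == "fwd") {
      bound <- min(c(cuts[cuts > cp], L))
      avail <- bound - cp
      if (avail < 1) return(NULL)
      c(cp, cp + min(round(len), avail))
    } else {
      bound <- max(c(cuts[cuts < cp], 0))
      avail <- cp - bound
      if (avail < 1) return(NULL)
      c(cp - min(round(len), avail), cp)
    }
  }
  with_seed(config$seed, {
    for (mol in seq_len(config$n_molecules)) {
      occurred <- runif(nrow(g)) < g$efficiency
      cuts <- sort(g$cut_pos[occurred])
      for (j in which(occurred)) {
        dir <- if (g$strand[j] == "-") "fwd" else "rev"
        len <- rlnorm(1, config$read_length_log_mean, config$read_length_log_sd)
        q <- max(0, rnorm(1, config$qscore_mean, config$qscore_sd))
        se <- clipped_read(g$cut_pos[j], dir, cuts, len)
        if (!is.null(se) && se[2] > se[1]) {
          emit(sprintf("mol%05d_%s", mol, g$name[j]),
               se[1], se[2], dir, q, "cut", g$name[j])
        }
      }
      if (config$background_rate > 0 && runif(1) < config$background_rate) {
        bp <- floor(runif(1, 0, L))
        dir <- sample(c("fwd", "rev"), 1)
        len <- rlnorm(1, config$read_length_log_mean, config$read_length_log_sd)
        q <- max(0, rnorm(1, config$qscore_mean, config$qscore_sd))
        se <- clipped_read(bp, dir, cuts, len)
        if (!is.null(se) && se[2] > se[1]) {
          emit(sprintf("mol%05d_bg", mol),
               se[1], se[2], dir, q, "background", NA_character_)
        }
      }
    }
  })
  data.frame(
    read_id = unlist(ids) %||% character(0),
    start = unlist(starts) %||% numeric(0),
    end = unlist(ends) %||% numeric(0),
    direction = unlist(dirs) %||% character(0),
    mean_q = unlist(qs) %||% numeric(0),
    origin = unlist(origins) %||% character(0),
    guide_name = unlist(guides) %||% character(0),
    stringsAsFactors = FALSE
  )
}

#' Filter reads by mean Qscore
#'
#' Keeps reads whose per-read mean quality is at or above the threshold
#' (boundary inclusive), preserving input order.
#'
#' @param reads Read table from [simulate_reads()].
#' @param qmin PASS threshold (default 9).
#' @return The filtered read table.
#' @export
apply_qscore_filter <- function(reads, qmin = 9) {
  reads[reads$mean_q >= qmin, , drop = FALSE]
}

#' Write simulated reads as FASTQ
#'
#' Bases are taken from the reference (reverse-complemented for `rev`
#' reads), substitution errors are injected at the Phred rate
#' `10^(-mean_q / 10)`, and base qualities are constant at
#' `round(mean_q)` in Sanger encoding.
#'
#' @param reads Read table from [simulate_reads()].
#' @param ref Reference sequence.
#' @param path Output FASTQ path.
#' @param seed Seed for the error-injection draws.
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(reads, ref, path, seed = 1) {
  s <- seq_as_character(ref)
  if (nrow(reads) && max(reads$end) > nchar(s)) {
    stop("reads extend beyond the reference")
  }
  seqs <- character(nrow(reads))
  quals <- character(nrow(reads))
  with_seed(seed, {
    for (i in seq_len(nrow(reads))) {
      b <- substr(s, reads$start[i] + 1, reads$end[i])
      n <- nchar(b)
      rate <- 10^(-reads$mean_q[i] / 10)
      nerr <- rbinom(1, n, rate)
      if (nerr > 0) {
        ch <- strsplit(b, "", fixed = TRUE)[[1]]
        at <- sample.int(n, nerr)
        for (p in at) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        }
        b <- paste(ch, collapse = "")
      }
      if (reads$direction[i] == "rev") b <- dna_revcomp(b)
      seqs[i] <- b
      qchar <- rawToChar(as.raw(33L + min(93L, as.integer(round(reads$mean_q[i])))))
      quals[i] <- strrep(qchar, n)
    }
  })
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- reads$read_id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write / read ground-truth read alignments
#'
#' Truth intervals are written as strict BED6 so that any BED-aware tool
#' (including [read_bed()]) can consume them: `read_id`, `start`, `end`,
#' name = `origin` (suffixed `:guide` for cut reads), score = `mean_q`,
#' strand = `+` for `fwd` / `-` for `rev`. [read_truth_alignments()]
#' restores the simulator's column layout.
#'
#' @param reads Read table from [simulate_reads()].
#' @param path Output path.
#' @return `path` invisibly; for [read_truth_alignments()], a `data.frame`
#'   with `read_id`, `start`, `end`, `direction`, `mean_q`, `origin`,
#'   `guide_name`.
#' @export
emit_truth_alignments <- function(reads, path) {
  name <- ifelse(is.na(reads$guide_name), reads$origin,
                 paste0(reads$origin, ":", reads$guide_name))
  lines <- paste(
    reads$read_id,
    format(reads$start, scientific = FALSE, trim = TRUE),
    format(reads$end, scientific = FALSE, trim = TRUE),
    name,
    sprintf("%.2f", reads$mean_q),
    ifelse(reads$direction == "fwd", "+", "-"),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname emit_truth_alignments
#' @export
read_truth_alignments <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("read_id", "start", "end", "name",
                                  "mean_q", "strand"))
  origin <- sub(":.*$", "", tab$name)
  guide <- ifelse(grepl(":", tab$name, fixed = TRUE),
                  sub("^[^:]*:", "", tab$name), NA_character_)
  data.frame(
    read_id = tab$read_id,
    start = tab$start,
    end = tab$end,
    direction = ifelse(tab$strand == "+", "fwd", "rev"),
    mean_q = tab$mean_q,
    origin = origin,
    guide_name = guide,
    stringsAsFactors = FALSE
  )
}
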