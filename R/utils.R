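# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (the "printed" convention, e.g. 12.68% for 9/71),
# unlike base round()'s round-half-even. Small epsilon guards against
# representation error in quotients like 59/71.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards; seed = NULL runs as-is.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# reverse complement of plain character DNA (uppercase ACGTN)
dna_revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

is_dna_string <- function(x) {
  all(grepl("^[ACGTN]+$", x))
}

# number of mismatched positions between two equal-length strings
str_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Normalise a reference argument (character, DNAString, DNAStringSet) to a
# single uppercase character string, keeping its name when available.
seq_as_character <- function(ref, which = 1L) {
  if (methods::is(ref, "DNAStringSet")) {
    s <- toupper(as.character(ref[[which]]))
    names(s) <- names(ref)[which]
    return(s)
  }
  if (methods::is(ref, "XString")) {
    return(toupper(as.character(ref)))
  }
  if (is.character(ref)) {
    s <- toupper(ref[[which]])
    names(s) <- names(ref)[which]
    return(s)
  }
  stop("unsupported sequence type: ", class(ref)[1])
}

seq_name_of <- function(ref, default = "seq1") {
  nm <- names(ref)
  if (is.null(nm) || is.na(nm[1]) || nm[1] == "") default else nm[1]
}

# Normalise a genome argument to a named character vector of sequences.
as_genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
  } else if (methods::is(genome, "XString")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("unsupported genome type: ", class(genome)[1])
  }
  if (length(out) == 0) stop("genome is empty")
  if (is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}
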