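#' Genomic region (0-based, half-open)
#'
#' The package-wide coordinate model is BED-style: `start` is 0-based
#' inclusive, `end` is exclusive, so a region's width is `end - start`.
#' Region strings and VCF positions (both 1-based inclusive as printed)
#' are converted at the boundary by [parse_region_string()] and
#' [read_variant_table()].
#'
#' @param seq_name Sequence (chromosome/contig) name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must be strictly greater than `start`.
#' @param label Optional free-text label.
#' @return An object of class `gregion`: a list with fields `seq_name`,
#'   `start`, `end`, `label`.
#' @examples
#' r <- gregion("chr1", 0, 100)
#' region_length(r)
#' @export
gregion <- function(seq_name, start, end, label = NULL) {
  stopifnot(is.character(seq_name), length(seq_name) == 1, nzchar(seq_name))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1 || length(end) != 1 || is.na(start) || is.na(end) ||
      start != trunc(start) || end != trunc(end)) {
    stop("start and end must be single integer values")
  }
  if (start < 0) stop("start must be >= 0")
  if (start >= end) {
    stop(sprintf("invalid region: start (%s) must be < end (%s)", start, end))
  }
  structure(
    list(seq_name = seq_name, start = start, end = end, label = label),
    class = "gregion"
  )
}

#' @rdname gregion
#' @param x A `gregion` object.
#' @export
region_length <- function(x) {
  stopifnot(inherits(x, "gregion"))
  x$end - x$start
}

#' @export
print.gregion <- function(x, ...) {
  cat(sprintf(
    "<gregion> %s (%s bp)%s\n",
    format_region_string(x),
    format(region_length(x), big.mark = ","),
    if (is.null(x$label)) "" else paste0(" [", x$label, "]")
  ))
  invisible(x)
}

#' Parse and format genome-browser region strings
#'
#' Region strings such as `"chr1:68,423,822-68,454,954"` use 1-based
#' inclusive coordinates with optional thousands separators. Parsing
#' converts to the internal 0-based half-open convention, so the example
#' yields a region of 31,133 bp. `format_region_string()` is the exact
#' inverse.
#'
#' @param text A region string `"<name>:<start>-<end>"`.
#' @return `parse_region_string()`: a [gregion()]; `format_region_string()`:
#'   a string.
#' @examples
#' r <- parse_region_string("chr1:68,423,822-68,454,954")
#' region_length(r)  # 31133
#' format_region_string(r)
#' @export
parse_region_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  m <- regmatches(
    text,
    regexec("^\\s*([^:[:space:]]+):([0-9,]+)-([0-9,]+)\\s*$", text)
  )[[1]]
  if (length(m) != 4) {
    stop("malformed region string: ", text,
         " (expected \"<name>:<start>-<end>\")")
  }
  p_start <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  p_end <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (p_start < 1 || p_end < 1) stop("coordinates must be positive: ", text)
  if (p_start > p_end) {
    stop(sprintf("inverted bounds in region string: %s > %s", m[3], m[4]))
  }
  gregion(m[2], p_start - 1, p_end)
}

#' @rdname parse_region_string
#' @param region A [gregion()].
#' @param big_mark Thousands separator used when printing coordinates.
#' @export
format_region_string <- function(region, big_mark = ",") {
  stopifnot(inherits(region, "gregion"))
  fmt <- function(x) format(x, big.mark = big_mark, scientific = FALSE, trim = TRUE)
  sprintf("%s:%s-%s", region$seq_name, fmt(region$start + 1), fmt(region$end))
}

# normalise a list of gregion or a data.frame to a data.frame with
# seq_name/start/end/label columns
as_region_df <- function(x) {
  if (inherits(x, "gregion")) x <- list(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    if (is.null(x$seq_name)) x$seq_name <- NA_character_
    if (is.null(x$label)) x$label <- NA_character_
    return(x[, c("seq_name", "start", "end", "label")])
  }
  stopifnot(is.list(x))
  data.frame(
    seq_name = vapply(x, function(r) r$seq_name, character(1)),
    start = vapply(x, function(r) r$start, numeric(1)),
    end = vapply(x, function(r) r$end, numeric(1)),
    label = vapply(x, function(r) r$label %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}
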