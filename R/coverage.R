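#' Per-base depth of coverage over a region
#'
#' Intervals are clipped to the region; `depth[b]` is the exact number of
#' intervals covering base `b`. Built on [IRanges::coverage()].
#'
#' @param intervals A list of [gregion()], a `data.frame` with
#'   `start`/`end` (and optionally `seq_name`) columns, or a read table
#'   from [simulate_reads()].
#' @param region The [gregion()] to profile.
#' @return A `depth_profile` object: list with `region` and integer vector
#'   `depth` of length `region_length(region)`.
#' @export
depth_profile <- function(intervals, region) {
  stopifnot(inherits(region, "gregion"))
  df <- as_region_df_or_reads(intervals)
  if (!all(is.na(df$seq_name)) &&
      any(df$seq_name != region$seq_name, na.rm = TRUE)) {
    stop("interval sequence names do not match the region (",
         region$seq_name, ")")
  }
  rs <- pmax(df$start, region$start)
  re <- pmin(df$end, region$end)
  keep <- rs < re
  ir <- IRanges::IRanges(start = rs[keep] - region$start + 1,
                         end = re[keep] - region$start)
  cov <- IRanges::coverage(ir, width = region_length(region))
  structure(
    list(region = region, depth = as.integer(cov)),
    class = "depth_profile"
  )
}

# accept read tables (which have start/end but no seq_name) as intervals
as_region_df_or_reads <- function(x) {
  if (is.data.frame(x) && !("seq_name" %in% names(x))) {
    x$seq_name <- NA_character_
  }
  as_region_df(x)
}

#' Depth summary statistics
#'
#' @param profile A [depth_profile()].
#' @return List with exact `min` and `max` and `mean` rounded half-up to
#'   2 decimals.
#' @export
depth_stats <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  d <- profile$depth
  if (!length(d)) stop("empty depth profile")
  list(min = min(d), mean = round_half_up(mean(d), 2), max = max(d))
}

#' Cumulative coverage at depth thresholds
#'
#' The percentage of region bases at or above each depth threshold —
#' the quantity plotted as a cumulative coverage curve.
#'
#' @param profile A [depth_profile()].
#' @param thresholds Non-negative integer depth cutoffs.
#' @return Named numeric vector of percentages (2 decimals, half-up),
#'   non-increasing in the threshold.
#' @export
cumulative_coverage <- function(profile, thresholds = c(1, 20, 60)) {
  stopifnot(inherits(profile, "depth_profile"), all(thresholds >= 0))
  out <- vapply(thresholds, function(t) {
    round_half_up(100 * mean(profile$depth >= t), 2)
  }, numeric(1))
  setNames(out, paste0("ge", thresholds))
}

#' Read-length N50
#'
#' The largest length L such that reads of length >= L together contain at
#' least half of all sequenced bases (descending-sort cumulative sum).
#'
#' @param lengths Positive integer read lengths.
#' @return The N50 in bp.
#' @examples
#' read_n50(c(8000, 8000, 1000))  # 8000
#' @export
read_n50 <- function(lengths) {
  if (!length(lengths)) stop("no read lengths supplied")
  if (any(lengths <= 0)) stop("read lengths must be positive")
  sl <- sort(lengths, decreasing = TRUE)
  sl[which(cumsum(sl) >= sum(sl) / 2)[1]]
}

#' Region QC summary
#'
#' The run-level statistics reported for an enrichment experiment: number
#' of reads intersecting the region (by >= 1 bp), their N50, min/mean/max
#' depth over the region, and cumulative coverage at the given thresholds.
#'
#' @param intervals Read intervals (see [depth_profile()]).
#' @param region Target [gregion()].
#' @param thresholds Depth cutoffs for [cumulative_coverage()].
#' @return A `qc_summary` list: `n_reads`, `n50`, `min_depth`,
#'   `mean_depth`, `max_depth`, `pct_at_or_above`.
#' @export
qc_summary <- function(intervals, region, thresholds = c(1, 20, 60)) {
  df <- as_region_df_or_reads(intervals)
  hit <- pmax(df$start, region$start) < pmin(df$end, region$end)
  if (!all(is.na(df$seq_name))) {
    hit <- hit & (is.na(df$seq_name) | df$seq_name == region$seq_name)
  }
  prof <- depth_profile(df[hit, , drop = FALSE], region)
  st <- depth_stats(prof)
  structure(
    list(
      n_reads = sum(hit),
      n50 = if (any(hit)) read_n50(df$end[hit] - df$start[hit]) else NA_integer_,
      min_depth = st$min, mean_depth = st$mean, max_depth = st$max,
      pct_at_or_above = cumulative_coverage(prof, thresholds)
    ),
    class = "qc_summary"
  )
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("<qc_summary>\n")
  cat(sprintf("  reads: %d\n", x$n_reads))
  cat(sprintf("  read N50 (bp): %s\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  depth min/mean/max: %s / %s / %s\n",
              x$min_depth, format(x$mean_depth, nsmall = 2), x$max_depth))
  for (nm in names(x$pct_at_or_above)) {
    cat(sprintf("  %% bases >= x%s: %.2f\n",
                sub("^ge", "", nm), x$pct_at_or_above[[nm]]))
  }
  invisible(x)
}

#' Write a QC summary TSV
#'
#' @param qc A [qc_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(qc, path) {
  rows <- data.frame(
    statistic = c("reads", "read_n50_bp", "min_depth", "mean_depth",
                  "max_depth",
                  paste0("pct_depth_", names(qc$pct_at_or_above))),
    value = c(qc$n_reads, qc$n50, qc$min_depth, qc$mean_depth, qc$max_depth,
              unname(qc$pct_at_or_above)),
    stringsAsFactors = FALSE
  )
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
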