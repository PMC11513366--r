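#' Expand a locus with symmetric flanks
#'
#' Cas9 excision fragments lose coverage right at the cut sites, so the
#' designed region extends a fixed flank (default 5 kb) beyond the locus on
#' each side.
#'
#' @param locus A [gregion()].
#' @param flank Flank width in bp (default 5000).
#' @return A [gregion()] longer by exactly `2 * flank`.
#' @examples
#' expand_with_flanks(parse_region_string("chr1:68,428,822-68,449,954"))
#' @export
expand_with_flanks <- function(locus, flank = 5000) {
  stopifnot(inherits(locus, "gregion"), flank >= 0)
  if (locus$start < flank) {
    stop("flank of ", flank, " bp would extend past the sequence origin")
  }
  gregion(locus$seq_name, locus$start - flank, locus$end + flank,
          label = locus$label)
}

#' Partition a region into tiling blocks
#'
#' The region is split into `n = ceiling(length / block_size)` contiguous
#' blocks of near-equal size; internal boundary k sits at
#' `start + round_half_up(k * length / n)`. Each block is served by one
#' opposite-strand guide pair.
#'
#' @param region A [gregion()].
#' @param block_size Target block size in bp (default 10000, minimum 1000).
#' @return A `data.frame` with columns `tile`, `seq_name`, `start`, `end`.
#' @examples
#' r <- gregion("chr1", 0, 31133)
#' build_tiles(r)  # 4 tiles, boundaries at 7783 / 15567 / 23350
#' @export
build_tiles <- function(region, block_size = 10000) {
  stopifnot(inherits(region, "gregion"))
  if (block_size < 1000) stop("block_size must be at least 1000 bp")
  len <- region_length(region)
  if (len < 23) stop("region too short to tile")
  n <- ceiling(len / block_size)
  bounds <- region$start + round_half_up((0:n) * len / n)
  data.frame(
    tile = seq_len(n),
    seq_name = region$seq_name,
    start = bounds[-(n + 1)],
    end = bounds[-1]
  )
}

# Lazy per-candidate off-target counting: compute mm columns for row i of
# the candidate table held in environment `env` (fields $cand, $genome),
# caching the result in place.
ensure_offtargets <- function(env, i) {
  if (is.na(env$cand$mm0[i])) {
    mm <- count_offtargets(env$cand[i, ], env$genome)
    env$cand[i, paste0("mm", 0:3)] <- as.list(mm)
  }
  unlist(env$cand[i, paste0("mm", 0:3)])
}

# Deterministic choice of one guide near `edge` on `strand`: among
# criteria-passing candidates with a cut within +/- w of the edge, take the
# highest efficiency (ties: smaller |cut - edge|, then lexicographically
# smaller protospacer); grow w from `window` by `window_step` up to
# `window_max`. `after`/`limit` optionally constrain the cut to lie in
# (after, after + limit], which keeps a pair's cut distance within one
# block. Returns the row index into env$cand, or stops.
pick_edge_guide <- function(env, strand, edge, criteria,
                            window, window_step, window_max,
                            after = NULL, limit = NULL) {
  cheap_ok <- env$cand$strand == strand &
    env$cand$gc_percent >= criteria$gc_min &
    env$cand$gc_percent <= criteria$gc_max &
    env$cand$self_complementarity <= criteria$max_self_complementarity &
    env$cand$efficiency >= criteria$min_efficiency
  if (!is.null(after)) {
    cheap_ok <- cheap_ok & env$cand$cut_pos > after &
      env$cand$cut_pos <= after + limit
  }
  for (w in seq(window, window_max, by = window_step)) {
    idx <- which(cheap_ok & abs(env$cand$cut_pos - edge) <= w)
    if (!length(idx)) next
    ord <- order(-env$cand$efficiency[idx],
                 abs(env$cand$cut_pos[idx] - edge),
                 env$cand$protospacer[idx])
    for (i in idx[ord]) {
      mm <- ensure_offtargets(env, i)
      if (sum(mm) < criteria$max_offtargets) return(i)
    }
  }
  stop(sprintf(
    "no criteria-passing %s-strand candidate within %d bp of position %s",
    strand, window_max, format(edge, scientific = FALSE)
  ))
}

#' Select the guide pair serving one tile
#'
#' Picks a minus-strand guide cutting near the tile's left edge and a
#' plus-strand guide cutting near its right edge (so reads initiated at
#' either cut run into the tile), each the best-efficiency candidate that
#' passes the criteria within a growing search window around the edge. The
#' plus-strand choice is additionally constrained so the pair's cut
#' distance does not exceed `block_size`.
#'
#' @param tile One row of [build_tiles()] output (or a list with
#'   `start`/`end`).
#' @param candidates Candidate table with cheap metrics attached
#'   ([add_guide_metrics()]; off-target columns may be `NA` and are filled
#'   lazily).
#' @param genome Off-target search space.
#' @param criteria A [criteria_config()].
#' @param window,window_step,window_max Edge search window (bp): start
#'   width, growth increment, and cap.
#' @param block_size Upper bound on the pair's cut distance.
#' @param after_cut Optional: cut position of the preceding tile's plus
#'   guide; the minus guide is then constrained to cut after it, keeping
#'   the panel's cut sites interleaved along the region.
#' @return A list with one-row data.frames `minus` and `plus`.
#' @export
select_pair_for_tile <- function(tile, candidates, genome,
                                 criteria = criteria_config(),
                                 window = 1500, window_step = 500,
                                 window_max = 5000, block_size = 10000,
                                 after_cut = NULL) {
  env <- new.env(parent = emptyenv())
  env$cand <- candidates
  env$genome <- genome
  i_minus <- pick_edge_guide(env, "-", tile$start, criteria,
                             window, window_step, window_max,
                             after = after_cut,
                             limit = if (is.null(after_cut)) NULL else block_size)
  i_plus <- pick_edge_guide(env, "+", tile$end, criteria,
                            window, window_step, window_max,
                            after = env$cand$cut_pos[i_minus],
                            limit = block_size)
  list(minus = env$cand[i_minus, ], plus = env$cand[i_plus, ])
}

#' Design a tiling guide panel over a locus
#'
#' Expands the locus with flanks, partitions it into blocks, and selects
#' one opposite-strand guide pair per block so that every selected guide
#' passes the criteria and consecutive cut sites sit less than `block_size`
#' apart. The procedure is deterministic for a fixed reference.
#'
#' @param ref Reference sequence (`DNAStringSet` or character).
#' @param locus Target [gregion()] (before flank expansion).
#' @param flank Flank width in bp added to each side (default 5000).
#' @param block_size Tiling block size in bp (default 10000).
#' @param criteria A [criteria_config()].
#' @param window,window_step,window_max Edge search window parameters
#'   (see [select_pair_for_tile()]).
#' @param genome Off-target search space; defaults to `ref`. Supply the
#'   full genome here when designing against a real assembly.
#' @return A `tiling_design` object: list with `region`, `locus`, `guides`
#'   (one row per selected guide with metrics, pair index and role),
#'   `criteria`, `block_size`.
#' @export
design_tiling <- function(ref, locus, flank = 5000, block_size = 10000,
                          criteria = criteria_config(),
                          window = 1500, window_step = 500,
                          window_max = 5000, genome = NULL) {
  region <- if (flank > 0) expand_with_flanks(locus, flank) else locus
  if (is.null(genome)) genome <- ref
  cand <- add_guide_metrics(enumerate_candidates(ref, region),
                            offtargets = FALSE)
  tiles <- build_tiles(region, block_size)
  env <- new.env(parent = emptyenv())
  env$cand <- cand
  env$genome <- genome
  rows <- list()
  prev_plus_cut <- NULL
  for (k in seq_len(nrow(tiles))) {
    i_minus <- pick_edge_guide(env, "-", tiles$start[k], criteria,
                               window, window_step, window_max,
                               after = prev_plus_cut, limit = block_size)
    i_plus <- pick_edge_guide(env, "+", tiles$end[k], criteria,
                              window, window_step, window_max,
                              after = env$cand$cut_pos[i_minus],
                              limit = block_size)
    prev_plus_cut <- env$cand$cut_pos[i_plus]
    for (role in c("minus", "plus")) {
      i <- if (role == "minus") i_minus else i_plus
      g <- env$cand[i, ]
      g$pair <- k
      g$role <- role
      rows[[length(rows) + 1]] <- g
    }
  }
  guides <- do.call(rbind, rows)
  guides <- guides[order(guides$cut_pos, match(guides$strand, c("+", "-"))), ]
  guides$name <- sprintf("g%d", seq_len(nrow(guides)))
  rownames(guides) <- NULL
  design <- structure(
    list(region = region, locus = locus, guides = guides,
         criteria = criteria, block_size = block_size),
    class = "tiling_design"
  )
  validate_design(design)
  design
}

#' @export
print.tiling_design <- function(x, ...) {
  cat(sprintf(
    "<tiling_design> %s: %d guide pairs (%d guides), block size %s bp\n",
    format_region_string(x$region), max(x$guides$pair), nrow(x$guides),
    format(x$block_size, big.mark = ",")
  ))
  invisible(x)
}

# Enforce the design invariants; called on every constructed design.
validate_design <- function(design) {
  g <- design$guides
  if (!all(passes_criteria(g, design$criteria))) {
    stop("internal error: a selected guide fails the criteria")
  }
  for (k in unique(g$pair)) {
    p <- g[g$pair == k, ]
    if (nrow(p) != 2 || length(unique(p$strand)) != 2) {
      stop("internal error: pair ", k, " is not an opposite-strand pair")
    }
    if (abs(diff(p$cut_pos)) > design$block_size) {
      stop("internal error: pair ", k, " cut distance exceeds block size")
    }
  }
  gaps <- diff(sort(g$cut_pos))
  if (length(gaps) && max(gaps) >= design$block_size) {
    stop("internal error: adjacent cut sites are >= ",
         design$block_size, " bp apart")
  }
  invisible(design)
}

# guide table accessor that tolerates either a design object or a raw table
design_guides <- function(design) {
  if (inherits(design, "tiling_design")) design$guides else design
}

#' Arrange designed guides into reagent pools
#'
#' Two layouts are supported. `"bricklayer"` separates overlapping
#' neighbours: odd-indexed pairs go to pool A and even-indexed pairs to
#' pool B, so no two guides of the same pair, and no two adjacent pairs,
#' share a pool. `"highway"` separates by cut direction: all minus-strand
#' guides go to pool C and all plus-strand guides to pool D.
#'
#' @param design A `tiling_design`.
#' @param scheme `"bricklayer"` or `"highway"`.
#' @return A `pool_layout` object: list with `scheme` and `pools` (named
#'   list of guide-name vectors; names A/B or C/D).
#' @export
assign_pools <- function(design, scheme = c("bricklayer", "highway")) {
  scheme <- match.arg(scheme)
  g <- design_guides(design)
  if (nrow(g) < 2) stop("design must contain at least one guide pair")
  pools <- if (scheme == "bricklayer") {
    list(A = g$name[g$pair %% 2 == 1], B = g$name[g$pair %% 2 == 0])
  } else {
    list(C = g$name[g$strand == "-"], D = g$name[g$strand == "+"])
  }
  structure(list(scheme = scheme, pools = pools), class = "pool_layout")
}

#' Tabulate a design (and its pool layouts)
#'
#' @param design A `tiling_design`.
#' @param layouts Optional list of [assign_pools()] results; each adds a
#'   `pool_<scheme>` column.
#' @return A `design_report` list: `guides` (one row per guide: name, tile,
#'   strand, 23-mer sequence, coordinates, metrics, pair cut distance, pool
#'   membership), `mean_pair_distance`, and `max_adjacent_distance` over
#'   consecutive cut sites.
#' @export
design_report <- function(design, layouts = NULL) {
  g <- design_guides(design)
  pair_dist <- vapply(g$pair, function(k) {
    abs(diff(g$cut_pos[g$pair == k]))
  }, numeric(1))
  tab <- data.frame(
    name = g$name,
    tile = g$pair,
    strand = g$strand,
    sequence = paste0(g$protospacer, g$pam),
    protospacer_start = g$protospacer_start,
    cut_pos = g$cut_pos,
    pair_distance = pair_dist,
    gc_percent = g$gc_percent,
    self_complementarity = g$self_complementarity,
    mm0 = g$mm0, mm1 = g$mm1, mm2 = g$mm2, mm3 = g$mm3,
    efficiency = g$efficiency,
    stringsAsFactors = FALSE
  )
  for (lay in layouts) {
    col <- paste0("pool_", lay$scheme)
    tab[[col]] <- NA_character_
    for (p in names(lay$pools)) {
      tab[[col]][tab$name %in% lay$pools[[p]]] <- p
    }
  }
  structure(
    list(
      guides = tab,
      mean_pair_distance = mean(pair_dist[!duplicated(g$pair)]),
      max_adjacent_distance = max(diff(sort(g$cut_pos)))
    ),
    class = "design_report"
  )
}

#' Write / read a design report TSV
#'
#' The TSV mirrors the per-guide table of [design_report()]; summary
#' distances are carried as `#`-prefixed header lines. [read_design()]
#' restores a guide table usable by [simulate_reads()] and
#' [assign_pools()].
#'
#' @param report A `design_report` (or `tiling_design`, tabulated first).
#' @param path Output path.
#' @return `path` invisibly; for [read_design()], the guide `data.frame`.
#' @export
write_design_report <- function(report, path) {
  if (inherits(report, "tiling_design")) report <- design_report(report)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mean_pair_distance=%s",
                     format(report$mean_pair_distance, scientific = FALSE)), con)
  writeLines(sprintf("# max_adjacent_distance=%s",
                     format(report$max_adjacent_distance, scientific = FALSE)), con)
  suppressWarnings(write.table(report$guides, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_design_report
#' @export
read_design <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  tab$protospacer <- substr(tab$sequence, 1, 20)
  tab$pam <- substr(tab$sequence, 21, 23)
  tab$pair <- tab$tile
  tab
}
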