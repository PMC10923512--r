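#' Amplicon panel design
#'
#' The targeted assay genotypes a handful of strain-diagnostic variants per
#' amplicon, spread along every chromosome so that chromosome identity
#' survives the loss of individual amplicons during whole-genome
#' amplification. Each chromosome is tiled into fixed intervals (7 Mb by
#' default, so the number of target loci scales with chromosome length) and
#' within each interval one target window is picked: a variant cluster
#' spanning at most `window_bp` whose `flank_bp` margins — the prospective
#' primer binding sites — contain no catalog variant at all.
#'
#' @name panel_design
NULL

#' Panel design configuration
#'
#' @param interval_bp Tiling interval per chromosome (default 7 Mb).
#' @param window_bp Maximum variant-cluster span per target window
#'   (default 120 bp).
#' @param flank_bp Variant-free margin on each side of the window, kept
#'   clear for primer binding (default 80 bp).
#' @param min_variants_per_window Preferred minimum variants per window
#'   (default 2); a bin with no multi-variant candidate falls back to
#'   single-variant windows.
#' @param include_chroms Optional character vector restricting design to
#'   these chromosomes (default: all in the map; note the female map
#'   already excludes Y).
#' @return A `panel_config` list.
#' @export
panel_config <- function(interval_bp = 7e6L, window_bp = 120L,
                         flank_bp = 80L, min_variants_per_window = 2L,
                         include_chroms = NULL) {
  if (window_bp < 1L) stop("window_bp must be >= 1")
  if (flank_bp < 0L) stop("flank_bp must be >= 0")
  if (interval_bp <= window_bp + 2L * flank_bp) {
    stop("interval_bp must exceed window_bp + 2*flank_bp")
  }
  if (min_variants_per_window < 1L) stop("min_variants_per_window must be >= 1")
  structure(list(interval_bp = as.numeric(interval_bp),
                 window_bp = as.integer(window_bp),
                 flank_bp = as.integer(flank_bp),
                 min_variants_per_window = as.integer(min_variants_per_window),
                 include_chroms = include_chroms),
            class = "panel_config")
}

new_panel <- function(regions, config) {
  rownames(regions) <- NULL
  structure(regions, config = config, class = c("amplicon_panel", "data.frame"))
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("amplicon panel: %d regions on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0L) {
    cat(sprintf("  variants/region: mean %.1f (min %d, max %d); mean amplicon %.0f bp\n",
                mean(x$n_variants), min(x$n_variants), max(x$n_variants),
                mean(x$amplicon_end - x$amplicon_start + 1)))
  }
  cat(sprintf("  interval %.1f Mb, window <= %d bp, flanks %d bp\n",
              cfg$interval_bp / 1e6, cfg$window_bp, cfg$flank_bp))
  invisible(x)
}

#' Design an amplicon panel over a consensus catalog
#'
#' Each chromosome is tiled into consecutive `interval_bp` bins anchored at
#' position 1. Within a bin, every candidate window is the maximal run of
#' catalog variants starting at one variant and extending while the span
#' stays within `window_bp` (window boundaries are the first and last
#' variant positions). A candidate is admissible when both `flank_bp`
#' margins are free of *any* catalog variant (checked genome-wide, so primer
#' sites stay variant-free) and its amplicon does not overlap the previously
#' selected region. Among admissible candidates with at least
#' `min_variants_per_window` variants (falling back to 1 if none), the
#' winner has the most variants, then the shortest span, then the leftmost
#' start. Bins without any admissible candidate yield no region.
#'
#' @param catalog A `consensus_catalog` (may be empty).
#' @param chrom_map A [chromosome_map()].
#' @param config A [panel_config()].
#' @return An `amplicon_panel`: data.frame with columns `chrom`, `bin`,
#'   `window_start`, `window_end`, `amplicon_start`, `amplicon_end`,
#'   `n_variants`, sorted by (chrom, window_start).
#' @export
design_panel <- function(catalog, chrom_map, config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  chroms <- chrom_map$chrom
  if (!is.null(config$include_chroms)) {
    chroms <- intersect(chroms, config$include_chroms)
  }
  empty <- data.frame(chrom = character(), bin = integer(),
                      window_start = integer(), window_end = integer(),
                      amplicon_start = integer(), amplicon_end = integer(),
                      n_variants = integer(), stringsAsFactors = FALSE)
  if (nrow(catalog) == 0L) return(new_panel(empty, config))
  check_positions(catalog$chrom, catalog$pos, chrom_map, "catalog variant")

  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    clen <- chrom_map$length_bp[chrom_map$chrom == chrom]
    pos <- sort(catalog$pos[catalog$chrom == chrom])
    if (length(pos) == 0L) next
    n_bins <- ceiling(clen / config$interval_bp)
    rows <- list()
    prev_amp_end <- -Inf
    for (b in seq_len(n_bins)) {
      lo <- (b - 1) * config$interval_bp + 1
      hi <- min(b * config$interval_bp, clen)
      inbin <- pos[pos >= lo & pos <= hi]
      if (length(inbin) == 0L) next
      cand <- enumerate_windows(inbin, pos, clen, config, prev_amp_end)
      if (nrow(cand) == 0L) next
      pick <- pick_window(cand, config$min_variants_per_window)
      pick$chrom <- chrom
      pick$bin <- b
      rows[[length(rows) + 1L]] <- pick
      prev_amp_end <- pick$amplicon_end
    }
    if (length(rows) > 0L) out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(new_panel(empty, config))
  res <- res[, c("chrom", "bin", "window_start", "window_end",
                 "amplicon_start", "amplicon_end", "n_variants")]
  res <- res[order(match(res$chrom, chrom_map$chrom), res$window_start), ]
  new_panel(res, config)
}

# internal: all admissible candidate windows in one bin.
# `inbin` are sorted variant positions inside the bin, `allpos` all sorted
# positions on the chromosome (flank purity is genome-wide).
enumerate_windows <- function(inbin, allpos, clen, config, prev_amp_end) {
  n <- length(inbin)
  ws <- integer(0); we <- integer(0); nv <- integer(0)
  for (i in seq_len(n)) {
    j <- max(which(inbin <= inbin[i] + config$window_bp - 1L))
    start <- inbin[i]; end <- inbin[j]
    amp_s <- max(1, start - config$flank_bp)
    amp_e <- min(clen, end + config$flank_bp)
    if (amp_s <= prev_amp_end) next
    # flanks must be variant-free against the whole catalog
    in_flank <- any(allpos >= start - config$flank_bp & allpos < start) ||
      any(allpos > end & allpos <= end + config$flank_bp)
    if (in_flank) next
    ws <- c(ws, start); we <- c(we, end); nv <- c(nv, j - i + 1L)
  }
  data.frame(window_start = ws, window_end = we, n_variants = nv,
             amplicon_start = pmax(1, ws - config$flank_bp),
             amplicon_end = pmin(clen, we + config$flank_bp))
}

# internal: tie-break — most variants, shortest span, leftmost start;
# candidates below the preferred variant minimum are only used as fallback
pick_window <- function(cand, min_variants) {
  pool <- cand[cand$n_variants >= min_variants, , drop = FALSE]
  if (nrow(pool) == 0L) pool <- cand
  span <- pool$window_end - pool$window_start
  ord <- order(-pool$n_variants, span, pool$window_start)
  pool[ord[1L], , drop = FALSE]
}

#' Validate a panel against its catalog
#'
#' Checks every region invariant: window span within the configured
#' maximum, at least one catalog variant per window with `n_variants`
#' matching the catalog, variant-free flanks, amplicons inside the
#' chromosome and mutually non-overlapping, regions sorted, and at most
#' `ceiling(length/interval_bp)` regions per chromosome.
#'
#' @param panel An `amplicon_panel`.
#' @param catalog The `consensus_catalog` it was designed from.
#' @param chrom_map A [chromosome_map()].
#' @return Character vector of human-readable violations; empty when the
#'   panel is valid.
#' @export
validate_panel <- function(panel, catalog, chrom_map) {
  cfg <- attr(panel, "config")
  v <- character(0)
  if (nrow(panel) == 0L) return(v)
  for (k in seq_len(nrow(panel))) {
    r <- panel[k, ]
    span <- r$window_end - r$window_start + 1L
    if (span > cfg$window_bp) {
      v <- c(v, sprintf("%s:%d-%d window span %d exceeds %d bp",
                        r$chrom, r$window_start, r$window_end, span,
                        cfg$window_bp))
    }
    cpos <- catalog$pos[catalog$chrom == r$chrom]
    nin <- sum(cpos >= r$window_start & cpos <= r$window_end)
    if (nin == 0L) {
      v <- c(v, sprintf("%s:%d-%d window contains no catalog variant",
                        r$chrom, r$window_start, r$window_end))
    } else if (nin != r$n_variants) {
      v <- c(v, sprintf("%s:%d-%d n_variants %d but catalog holds %d",
                        r$chrom, r$window_start, r$window_end,
                        r$n_variants, nin))
    }
    fl <- cpos[(cpos >= r$window_start - cfg$flank_bp & cpos < r$window_start) |
                 (cpos > r$window_end & cpos <= r$window_end + cfg$flank_bp)]
    if (length(fl) > 0L) {
      v <- c(v, sprintf("%s:%d-%d flank contains catalog variant at %s:%d",
                        r$chrom, r$window_start, r$window_end, r$chrom, fl[1L]))
    }
    clen <- chrom_map$length_bp[chrom_map$chrom == r$chrom]
    if (length(clen) == 0L) {
      v <- c(v, sprintf("region on unknown chromosome %s", r$chrom))
    } else if (r$amplicon_start < 1 || r$amplicon_end > clen) {
      v <- c(v, sprintf("%s:%d-%d amplicon outside chromosome",
                        r$chrom, r$amplicon_start, r$amplicon_end))
    }
  }
  for (chrom in unique(panel$chrom)) {
    p <- panel[panel$chrom == chrom, ]
    if (is.unsorted(p$window_start, strictly = TRUE)) {
      v <- c(v, sprintf("regions on %s not sorted", chrom))
    }
    if (nrow(p) > 1L &&
        any(p$amplicon_start[-1L] <= p$amplicon_end[-nrow(p)])) {
      v <- c(v, sprintf("overlapping amplicons on %s", chrom))
    }
    clen <- chrom_map$length_bp[chrom_map$chrom == chrom]
    if (length(clen) == 1L && nrow(p) > ceiling(clen / cfg$interval_bp)) {
      v <- c(v, sprintf("%s carries more regions than bins", chrom))
    }
  }
  v
}

#' Panel loci
#'
#' Catalog variants falling inside panel target windows — the loci the
#' assay actually genotypes.
#'
#' @param panel An `amplicon_panel`.
#' @param catalog A `consensus_catalog`.
#' @return Data.frame `chrom`, `pos`, `ref`, `alt` sorted like the catalog.
#' @export
panel_loci <- function(panel, catalog) {
  if (nrow(panel) == 0L || nrow(catalog) == 0L) {
    return(catalog[integer(0), c("chrom", "pos", "ref", "alt")])
  }
  keep <- logical(nrow(catalog))
  for (k in seq_len(nrow(panel))) {
    keep <- keep | (catalog$chrom == panel$chrom[k] &
                      catalog$pos >= panel$window_start[k] &
                      catalog$pos <= panel$window_end[k])
  }
  out <- as.data.frame(catalog)[keep, c("chrom", "pos", "ref", "alt")]
  rownames(out) <- NULL
  out
}

#' Write panel intervals as BED
#'
#' Standard 0-based half-open BED with columns chrom, start, end, name,
#' score (variant count), strand.
#'
#' @param panel An `amplicon_panel`.
#' @param path Output path.
#' @param what `"amplicon"` (default) or `"window"` intervals.
#' @export
write_panel_bed <- function(panel, path, what = c("amplicon", "window")) {
  what <- match.arg(what)
  s <- if (what == "amplicon") panel$amplicon_start else panel$window_start
  e <- if (what == "amplicon") panel$amplicon_end else panel$window_end
  bed <- data.frame(chrom = panel$chrom, start = s - 1L, end = e,
                    name = sprintf("%s_bin%d", panel$chrom, panel$bin),
                    score = panel$n_variants, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
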