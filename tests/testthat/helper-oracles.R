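`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles. These deliberately reimplement the
# rules in the plainest possible way and are kept free of package
# internals beyond public accessors.

# per-site consensus rule, evaluated site by site with explicit loops
oracle_consensus <- function(callsets, min_sources) {
  sites <- unique(do.call(rbind, lapply(callsets, function(cs) {
    data.frame(chrom = cs$chrom, pos = cs$pos, stringsAsFactors = FALSE)
  })))
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    n_support <- 0L
    contradicted <- FALSE
    for (cs in callsets) {
      j <- which(cs$chrom == sites$chrom[i] & cs$pos == sites$pos[i])
      if (length(j) == 0L) next
      if (cs$gt_a[j] == "HOM_REF" && cs$gt_b[j] == "HOM_ALT") {
        n_support <- n_support + 1L
      }
      if (cs$gt_a[j] %in% c("HET", "HOM_ALT") ||
          cs$gt_b[j] %in% c("HET", "HOM_REF")) {
        contradicted <- TRUE
      }
    }
    keep[i] <- n_support >= min_sources && !contradicted
  }
  out <- sites[keep, ]
  out[order(out$chrom, out$pos), ]
}

# exhaustive panel-design oracle: same candidate definition (maximal
# variant cluster from each start) and tie-break, written as plain loops
oracle_panel <- function(catalog, map, config) {
  regions <- list()
  for (chrom in map$chrom) {
    clen <- map$length_bp[map$chrom == chrom]
    allpos <- sort(catalog$pos[catalog$chrom == chrom])
    if (length(allpos) == 0L) next
    prev_end <- -Inf
    for (b in seq_len(ceiling(clen / config$interval_bp))) {
      lo <- (b - 1) * config$interval_bp + 1
      hi <- min(b * config$interval_bp, clen)
      inbin <- allpos[allpos >= lo & allpos <= hi]
      best <- NULL
      for (fallback in c(FALSE, TRUE)) {
        for (i in seq_along(inbin)) {
          js <- which(inbin >= inbin[i] &
                        inbin <= inbin[i] + config$window_bp - 1)
          j <- max(js)
          start <- inbin[i]; end <- inbin[j]; nv <- length(js)
          if (!fallback && nv < config$min_variants_per_window) next
          amp_s <- max(1, start - config$flank_bp)
          if (amp_s <= prev_end) next
          dirty <- any((allpos >= start - config$flank_bp & allpos < start) |
                         (allpos > end & allpos <= end + config$flank_bp))
          if (dirty) next
          cand <- list(start = start, end = end, nv = nv)
          if (is.null(best) ||
              cand$nv > best$nv ||
              (cand$nv == best$nv &&
                 (cand$end - cand$start < best$end - best$start ||
                    (cand$end - cand$start == best$end - best$start &&
                       cand$start < best$start)))) {
            best <- cand
          }
        }
        if (!is.null(best)) break
      }
      if (!is.null(best)) {
        prev_end <- min(clen, best$end + config$flank_bp)
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = chrom, bin = b, window_start = best$start,
                     window_end = best$end, n_variants = best$nv,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(regions) == 0L) {
    return(data.frame(chrom = character(), bin = integer(),
                      window_start = integer(), window_end = integer(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, regions)
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n, n_x) rank assignments (tie-free data only)
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  subsets <- utils::combn(nx + ny, nx)
  ws <- apply(subsets, 2, function(s) sum(seq_len(nx + ny)[s]) -
                nx * (nx + 1) / 2)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  list(W = w_obs, p = p)
}

# strain of a mosaic chromatid at given positions: start strain flipped
# at each breakpoint to the left
mosaic_strain <- function(pos, breakpoints, start_strain) {
  flips <- vapply(pos, function(p) sum(breakpoints < p), numeric(1))
  ifelse(flips %% 2 == 0, start_strain,
         ifelse(start_strain == "A", "B", "A"))
}

# truth-projection oracle for crossover detection: expected switch count
# at panel resolution, applying single-absorption and the >=2-consecutive
# block rule to the true locus strains
oracle_projected_switches <- function(pos, breakpoints, start_strain) {
  s <- mosaic_strain(pos, breakpoints, start_strain)
  r <- rle(s)
  kept <- r$values[r$lengths >= 2]
  if (length(kept) == 0L) return(0L)
  merged <- kept[c(TRUE, kept[-1] != kept[-length(kept)])]
  length(merged) - 1L
}
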