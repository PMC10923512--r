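#' Single-cell genotype calling and chromosome-origin inference
#'
#' Whole-genome-amplified single-cell DNA suffers allelic dropout, so
#' per-locus calls use conservative depth floors: homozygous loci need at
#' least 12 reads of the called allele and heterozygous loci at least 24
#' total reads; anything shallower is treated as not amplified and excluded
#' from chromosome-origin inference. Chromosome identity is then a
#' consensus across the chromosome's informative loci, which tolerates the
#' loss of individual amplicons.
#'
#' @name genotype_inference
NULL

#' Genotype-calling configuration
#'
#' @param min_hom_depth Minimum depth of the called allele for a homozygous
#'   call (default 12).
#' @param min_het_depth Minimum total depth for a heterozygous call
#'   (default 24; must be >= `min_hom_depth`).
#' @param min_minor_fraction Minimum minor-allele fraction for a
#'   heterozygous call (default 0.2).
#' @param max_contrary_fraction Maximum opposite-allele fraction tolerated
#'   in a homozygous call (default 0.05).
#' @return A `genotype_config` list.
#' @export
genotype_config <- function(min_hom_depth = 12L, min_het_depth = 24L,
                            min_minor_fraction = 0.2,
                            max_contrary_fraction = 0.05) {
  if (min_hom_depth < 1L || min_het_depth < min_hom_depth) {
    stop("need min_het_depth >= min_hom_depth >= 1")
  }
  if (min_minor_fraction < 0 || min_minor_fraction > 0.5 ||
      max_contrary_fraction < 0 || max_contrary_fraction > 0.5) {
    stop("fractions must lie in [0, 0.5]")
  }
  structure(list(min_hom_depth = as.integer(min_hom_depth),
                 min_het_depth = as.integer(min_het_depth),
                 min_minor_fraction = min_minor_fraction,
                 max_contrary_fraction = max_contrary_fraction),
            class = "genotype_config")
}

#' Call a locus genotype from allele depths
#'
#' Vectorized rule: `HET` iff total depth >= `min_het_depth` and the minor
#' allele fraction >= `min_minor_fraction`; otherwise `HOM_A` iff the
#' reference (strain A) depth >= `min_hom_depth` with the alternate
#' fraction <= `max_contrary_fraction` (`HOM_B` symmetric); otherwise
#' `NO_CALL`.
#'
#' @param ref_depth,alt_depth Non-negative integer depth vectors.
#' @param config A [genotype_config()].
#' @return Character vector in `{"HOM_A", "HOM_B", "HET", "NO_CALL"}`.
#' @export
call_locus_genotype <- function(ref_depth, alt_depth,
                                config = genotype_config()) {
  if (any(ref_depth < 0) || any(alt_depth < 0)) {
    stop("allele depths must be non-negative")
  }
  total <- ref_depth + alt_depth
  minor <- pmin(ref_depth, alt_depth)
  safe_tot <- pmax(total, 1L)
  call <- rep("NO_CALL", length(total))
  het <- total >= config$min_het_depth &
    minor / safe_tot >= config$min_minor_fraction
  hom_a <- !het & ref_depth >= config$min_hom_depth &
    alt_depth / safe_tot <= config$max_contrary_fraction
  hom_b <- !het & alt_depth >= config$min_hom_depth &
    ref_depth / safe_tot <= config$max_contrary_fraction
  call[het] <- "HET"
  call[hom_a] <- "HOM_A"
  call[hom_b] <- "HOM_B"
  call
}

#' Infer chromosome origin from ordered locus calls
#'
#' Classifies one chromosome of one sample from its position-ordered
#' genotype calls:
#' * `ABSENT` — fewer than `min_informative` informative (non-`NO_CALL`)
#'   loci;
#' * `BOTH` — at least two `HET` loci (both homologs present);
#' * `SINGLE_A` / `SINGLE_B` — one homolog: all retained homozygous blocks
#'   agree on a strain (isolated discordant loci are absorbed as
#'   dropout/error artifacts);
#' * `RECOMBINANT_SINGLE` — one chromatid with at least two alternating
#'   strain blocks, each supported by >= 2 consecutive concordant loci;
#' * `AMBIGUOUS` — anything else.
#'
#' @param pos Locus positions, strictly increasing.
#' @param call Genotype calls from [call_locus_genotype()], same order.
#' @param min_informative Minimum informative loci to call a chromosome
#'   present (default 2).
#' @return An `origin_profile` list: `content_state`, `switch_count`,
#'   `informative`, `n_het`, and `blocks` (data.frame `strain`,
#'   `start_pos`, `end_pos` of retained homozygosity blocks).
#' @export
infer_chromosome_origin <- function(pos, call, min_informative = 2L) {
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("locus positions must be strictly increasing")
  }
  inf_mask <- call != "NO_CALL"
  informative <- sum(inf_mask)
  n_het <- sum(call == "HET")
  hom_mask <- call %in% c("HOM_A", "HOM_B")
  hom_strain <- ifelse(call[hom_mask] == "HOM_A", "A", "B")
  hom_pos <- pos[hom_mask]

  blocks <- data.frame(strain = character(), start_pos = numeric(),
                       end_pos = numeric(), stringsAsFactors = FALSE)
  state <- "AMBIGUOUS"
  switches <- 0L

  if (informative < min_informative) {
    state <- "ABSENT"
  } else if (n_het >= 2L) {
    state <- "BOTH"
  } else if (length(hom_strain) == 0L) {
    state <- "AMBIGUOUS"
  } else {
    r <- rle(hom_strain)
    keep <- r$lengths >= 2L
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (!any(keep)) {
      # no multi-locus block: callable only if every hom call agrees
      if (length(unique(hom_strain)) == 1L) {
        state <- paste0("SINGLE_", hom_strain[1L])
        blocks <- data.frame(strain = hom_strain[1L],
                             start_pos = hom_pos[1L],
                             end_pos = hom_pos[length(hom_pos)],
                             stringsAsFactors = FALSE)
      }
    } else {
      ks <- r$values[keep]
      # merge consecutive retained blocks of the same strain (isolated
      # discordant singles between them are absorbed)
      merged_strain <- ks[c(TRUE, ks[-1L] != ks[-length(ks)])]
      mkeep <- which(keep)
      grp <- cumsum(c(TRUE, ks[-1L] != ks[-length(ks)]))
      bstart <- tapply(hom_pos[starts[mkeep]], grp, min)
      bend <- tapply(hom_pos[ends[mkeep]], grp, max)
      blocks <- data.frame(strain = merged_strain,
                           start_pos = as.numeric(bstart),
                           end_pos = as.numeric(bend),
                           stringsAsFactors = FALSE)
      if (nrow(blocks) == 1L) {
        state <- paste0("SINGLE_", blocks$strain[1L])
      } else {
        state <- "RECOMBINANT_SINGLE"
        switches <- nrow(blocks) - 1L
      }
    }
  }
  structure(list(content_state = state, switch_count = switches,
                 informative = as.integer(informative),
                 n_het = as.integer(n_het), blocks = blocks),
            class = "origin_profile")
}

#' @export
print.origin_profile <- function(x, ...) {
  cat(sprintf("origin profile: %s (%d informative loci, %d het, %d switch(es))\n",
              x$content_state, x$informative, x$n_het, x$switch_count))
  invisible(x)
}

#' Crossover breakpoint intervals of a profile
#'
#' For a `RECOMBINANT_SINGLE` profile, each switch between adjacent strain
#' blocks yields the interval from the last locus of one block to the
#' first locus of the next; all other content states return no intervals
#' (crossovers are undefined for two-homolog or absent content).
#'
#' @param profile An `origin_profile` from [infer_chromosome_origin()].
#' @return Data.frame `start`, `end`, `from_strain`, `to_strain` (possibly
#'   empty).
#' @export
detect_crossovers <- function(profile) {
  stopifnot(inherits(profile, "origin_profile"))
  empty <- data.frame(start = numeric(), end = numeric(),
                      from_strain = character(), to_strain = character(),
                      stringsAsFactors = FALSE)
  if (profile$content_state != "RECOMBINANT_SINGLE") return(empty)
  b <- profile$blocks
  n <- nrow(b)
  data.frame(start = b$end_pos[-n], end = b$start_pos[-1L],
             from_strain = b$strain[-n], to_strain = b$strain[-1L],
             stringsAsFactors = FALSE)
}

#' Profile every sample x chromosome of an observation table
#'
#' Calls genotypes at every locus and infers one origin profile per sample
#' and chromosome. Chromosomes of the map without any observed locus in a
#' sample are reported `ABSENT` with zero informative loci.
#'
#' @param observations Long observation table (`sample_id`, `role`,
#'   `chrom`, `pos`, `ref_depth`, `alt_depth`; an `embryo_id`/`oocyte_id`
#'   column is carried through when present).
#' @param chrom_map A [chromosome_map()].
#' @param config A [genotype_config()].
#' @param min_informative Passed to [infer_chromosome_origin()].
#' @return Data.frame with one row per sample x chromosome: `sample_id`,
#'   `role`, `chrom`, `content_state`, `switch_count`, `informative`,
#'   `n_het`, plus the id column if present; profiles (with blocks) are
#'   attached as the `profiles` attribute, keyed `sample_id:chrom`.
#' @export
profile_cohort <- function(observations, chrom_map = mouse_chrom_map(),
                           config = genotype_config(),
                           min_informative = 2L) {
  obs <- observations
  obs$call <- call_locus_genotype(obs$ref_depth, obs$alt_depth, config)
  id_col <- intersect(c("embryo_id", "oocyte_id"), names(obs))[1]
  ord <- order(obs$sample_id, match(obs$chrom, chrom_map$chrom), obs$pos)
  obs <- obs[ord, ]
  groups <- split(seq_len(nrow(obs)),
                  list(sample = obs$sample_id, chrom = obs$chrom),
                  drop = TRUE)
  samples <- unique(obs[, c("sample_id", "role",
                            if (!is.na(id_col)) id_col)])
  grid <- merge(samples, data.frame(chrom = chrom_map$chrom), by = NULL)
  profs <- vector("list", nrow(grid))
  names(profs) <- paste(grid$sample_id, grid$chrom, sep = ":")
  res <- grid
  res$content_state <- "ABSENT"
  res$switch_count <- 0L
  res$informative <- 0L
  res$n_het <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- groups[[paste(grid$sample_id[i], grid$chrom[i], sep = ".")]]
    if (is.null(g)) {
      profs[[i]] <- infer_chromosome_origin(numeric(0), character(0),
                                            min_informative)
      next
    }
    p <- infer_chromosome_origin(obs$pos[g], obs$call[g], min_informative)
    profs[[i]] <- p
    res$content_state[i] <- p$content_state
    res$switch_count[i] <- p$switch_count
    res$informative[i] <- p$informative
    res$n_het[i] <- p$n_het
  }
  res <- res[order(res$sample_id, match(res$chrom, chrom_map$chrom)), ]
  profs <- profs[paste(res$sample_id, res$chrom, sep = ":")]
  rownames(res) <- NULL
  structure(res, profiles = profs)
}
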