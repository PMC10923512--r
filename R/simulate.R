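#' Simulated premature-division cohorts
#'
#' The generator replaces the study's raw sequencing with cohorts whose
#' statistical structure matches what the analysis assumes. Each embryo is a
#' nonreplicated diploid (2n2c) somatic genome partitioned at premature
#' division: per homolog pair, either one homolog goes to the second polar
#' body (PB2) and one to the zygote (*proper* segregation) or both land on
#' the same side. Observed data are per-variant allele depths for the trio
#' (PB2 plus two blastomeres sharing the zygote genome), with
#' negative-binomial amplicon depth, per-allele whole-genome-amplification
#' dropout, and per-base sequencing error.
#'
#' @name synthetic_data
NULL

#' Segregation model configuration
#'
#' Embryo-level pairing-fidelity mixture: an embryo draws a fidelity `phi`
#' from `fidelity_mix`; each pair then segregates properly with probability
#' `phi + (1 - phi) * p_random_proper` (so `phi = 0` is the pure random
#' model with a 50% per-pair proper chance, `phi = 1` faithful
#' meiosis-I-like segregation). A nonsegregating pair stays in the zygote
#' with probability `retention_bias`, otherwise both homologs are extruded
#' into the PB2.
#'
#' @param background `"HYBRID"` (sequence-divergent homologs, e.g. B6/FVB),
#'   `"INBRED"` (identical homologs), or `"FERTILIZED_INBRED"` (inbred
#'   somatic genome plus a sperm haploid set of the other strain in the
#'   zygote).
#' @param p_random_proper Per-pair proper probability in the random mode
#'   (0.5: each chromatid is an independent fair coin).
#' @param fidelity_mix Data.frame with columns `fraction` (summing to 1)
#'   and `phi`; one row per mixture component.
#' @param retention_bias Probability that a nonsegregating pair stays in
#'   the zygote (0.5 = no bias).
#' @param somatic_strain Strain of the somatic genome for inbred
#'   backgrounds (default `"FVB"`).
#' @param sperm_strain Strain of the fertilizing sperm (default `"B6"`).
#' @return A `segregation_config` list.
#' @export
segregation_config <- function(background = c("HYBRID", "INBRED",
                                              "FERTILIZED_INBRED"),
                               p_random_proper = 0.5,
                               fidelity_mix = data.frame(fraction = 1,
                                                         phi = 0),
                               retention_bias = 0.5,
                               somatic_strain = "FVB",
                               sperm_strain = "B6") {
  background <- match.arg(background)
  stopifnot(is.data.frame(fidelity_mix),
            all(c("fraction", "phi") %in% names(fidelity_mix)))
  if (abs(sum(fidelity_mix$fraction) - 1) > 1e-8) {
    stop("fidelity_mix fractions must sum to 1")
  }
  probs <- c(p_random_proper, retention_bias, fidelity_mix$phi,
             fidelity_mix$fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  structure(list(background = background,
                 p_random_proper = p_random_proper,
                 fidelity_mix = fidelity_mix,
                 retention_bias = retention_bias,
                 somatic_strain = somatic_strain,
                 sperm_strain = sperm_strain),
            class = "segregation_config")
}

#' Fidelity equivalent of a target proper probability
#'
#' Inverts `p_eff = phi + (1 - phi) * p_random_proper`, giving the fidelity
#' that yields a desired effective per-pair proper probability.
#'
#' @param p_proper Target effective proper probability (>= `p_random_proper`).
#' @param p_random_proper Random-mode proper probability (default 0.5).
#' @return Fidelity value(s) in \[0, 1\].
#' @export
fidelity_for_proper <- function(p_proper, p_random_proper = 0.5) {
  if (any(p_proper < p_random_proper - 1e-12) || any(p_proper > 1)) {
    stop("p_proper must lie in [p_random_proper, 1]")
  }
  pmin(1, pmax(0, (p_proper - p_random_proper) / (1 - p_random_proper)))
}

#' Inbred-like fidelity mixture
#'
#' Two-component mixture calibrated to the inbred cohort's joint pattern: a
#' 0.19 fraction of embryos segregate all pairs faithfully (complete
#' haploidization) while the remainder segregate each pair properly with
#' probability 0.63, giving a cohort mean of 20*(0.19 + 0.81*0.63) = 14
#' proper pairs. A single per-pair probability cannot reproduce both the
#' mean of 14 and a 19% all-20-proper rate under independence.
#'
#' @param p_random_proper Random-mode proper probability (default 0.5).
#' @return A `fidelity_mix` data.frame usable in [segregation_config()].
#' @export
inbred_like_mix <- function(p_random_proper = 0.5) {
  data.frame(fraction = c(0.19, 0.81),
             phi = fidelity_for_proper(c(1.0, 0.63), p_random_proper))
}

#' Sequencing-noise configuration
#'
#' @param mean_depth Target mean amplicon coverage (default 250, the
#'   assay's design depth).
#' @param depth_dispersion Negative-binomial size parameter; `Inf` gives a
#'   constant depth equal to `mean_depth` (deterministic limit).
#' @param allelic_dropout_rate Per-locus, per-allele probability that
#'   whole-genome amplification drops every read of one allele
#'   (default 0.1).
#' @param per_base_error Per-read probability of reading the opposite
#'   allele (default 0.002).
#' @return A `noise_config` list.
#' @export
noise_config <- function(mean_depth = 250, depth_dispersion = 8,
                         allelic_dropout_rate = 0.1,
                         per_base_error = 0.002) {
  if (mean_depth <= 0 || depth_dispersion <= 0) {
    stop("mean_depth and depth_dispersion must be positive")
  }
  if (allelic_dropout_rate < 0 || allelic_dropout_rate > 1 ||
      per_base_error < 0 || per_base_error > 1) {
    stop("rates must lie in [0, 1]")
  }
  structure(list(mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 allelic_dropout_rate = allelic_dropout_rate,
                 per_base_error = per_base_error),
            class = "noise_config")
}

#' Noise-free observation settings
#'
#' Constant depth, no dropout, no error: downstream inference must recover
#' truth exactly under these settings.
#'
#' @param depth Constant per-locus depth (default 250).
#' @export
noiseless_config <- function(depth = 250) {
  noise_config(mean_depth = depth, depth_dispersion = Inf,
               allelic_dropout_rate = 0, per_base_error = 0)
}

#' Simulate segregation truth for a cohort
#'
#' Draws, per embryo, a fidelity from the mixture and, per homolog pair,
#' the destination of both single-chromatid homologs. Each pair contributes
#' exactly two chromatids across PB2 and zygote (conservation).
#'
#' @param n_embryos Number of embryos.
#' @param seg_config A [segregation_config()].
#' @param chrom_map A [chromosome_map()] (default [mouse_chrom_map()]).
#' @param seed Optional RNG seed.
#' @return Data.frame with one row per embryo x chromosome pair: columns
#'   `embryo_id`, `chrom`, `phi`, `proper`, `pb2_a`, `pb2_b`, `zyg_a`,
#'   `zyg_b` (0/1 copies of homolog A and homolog B on each side).
#' @export
simulate_cohort_truth <- function(n_embryos, seg_config,
                                  chrom_map = mouse_chrom_map(),
                                  seed = NULL) {
  stopifnot(inherits(seg_config, "segregation_config"))
  if (!is.null(seed)) set.seed(seed)
  n_pairs <- nrow(chrom_map)
  comp <- sample.int(nrow(seg_config$fidelity_mix), n_embryos, replace = TRUE,
                     prob = seg_config$fidelity_mix$fraction)
  phi_e <- seg_config$fidelity_mix$phi[comp]
  n <- n_embryos * n_pairs
  phi <- rep(phi_e, each = n_pairs)
  p_eff <- phi + (1 - phi) * seg_config$p_random_proper
  proper <- stats::runif(n) < p_eff
  orient <- stats::runif(n) < 0.5           # proper pairs: homolog A to PB2?
  both_zyg <- stats::runif(n) < seg_config$retention_bias
  pb2_a <- ifelse(proper, as.integer(orient), ifelse(both_zyg, 0L, 1L))
  pb2_b <- ifelse(proper, 1L - as.integer(orient), ifelse(both_zyg, 0L, 1L))
  data.frame(embryo_id = rep(seq_len(n_embryos), each = n_pairs),
             chrom = rep(chrom_map$chrom, times = n_embryos),
             phi = phi, proper = proper,
             pb2_a = pb2_a, pb2_b = pb2_b,
             zyg_a = 1L - pb2_a, zyg_b = 1L - pb2_b,
             stringsAsFactors = FALSE)
}

#' Per-embryo truth summary
#'
#' @param truth Output of [simulate_cohort_truth()].
#' @return Data.frame `embryo_id`, `n_proper`, `n_retained_chromatids`,
#'   `complete_haploidization`.
#' @export
truth_summary <- function(truth) {
  n_proper <- tapply(truth$proper, truth$embryo_id, sum)
  n_ret <- tapply(truth$zyg_a + truth$zyg_b, truth$embryo_id, sum)
  n_pairs <- tapply(truth$proper, truth$embryo_id, length)
  data.frame(embryo_id = as.integer(names(n_proper)),
             n_proper = as.integer(n_proper),
             n_retained_chromatids = as.integer(n_ret),
             complete_haploidization = as.integer(n_proper) ==
               as.integer(n_pairs),
             row.names = NULL)
}

# internal: allele-depth emission for one vector of loci.
# a_cop / b_cop are copy numbers of the strain-A (ref) and strain-B (alt)
# allele carried at each locus; returns ref/alt observed depths.
emit_depths <- function(a_cop, b_cop, noise) {
  n <- length(a_cop)
  tot <- integer(n)
  present <- (a_cop + b_cop) > 0
  np <- sum(present)
  if (np > 0L) {
    tot[present] <- if (is.finite(noise$depth_dispersion)) {
      stats::rnbinom(np, size = noise$depth_dispersion, mu = noise$mean_depth)
    } else rep(round(noise$mean_depth), np)
  }
  pref <- ifelse(present, a_cop / pmax(1L, a_cop + b_cop), 0)
  ref <- stats::rbinom(n, tot, pref)
  alt <- tot - ref
  if (noise$allelic_dropout_rate > 0) {
    ref[a_cop > 0 & stats::runif(n) < noise$allelic_dropout_rate] <- 0L
    alt[b_cop > 0 & stats::runif(n) < noise$allelic_dropout_rate] <- 0L
  }
  if (noise$per_base_error > 0) {
    keep_r <- stats::rbinom(n, ref, 1 - noise$per_base_error)
    flip_a <- stats::rbinom(n, alt, noise$per_base_error)
    new_ref <- keep_r + flip_a
    alt <- (ref - keep_r) + (alt - flip_a)
    ref <- new_ref
  }
  data.frame(ref_depth = as.integer(ref), alt_depth = as.integer(alt))
}

#' Emit trio allele-depth observations for a cohort truth
#'
#' Converts per-pair chromatid destinations into allele copy numbers at
#' every panel locus per trio sample, then samples depths under the noise
#' model. The two blastomeres carry the identical zygote genome with
#' independent noise. For inbred backgrounds both homologs carry the
#' somatic strain's allele; for fertilized inbred embryos the zygote
#' additionally carries one sperm-strain copy of every chromosome.
#'
#' @param truth Output of [simulate_cohort_truth()].
#' @param catalog A `consensus_catalog`.
#' @param panel An `amplicon_panel` designed from `catalog`.
#' @param noise A [noise_config()].
#' @param seg_config The [segregation_config()] used for the truth.
#' @param seed Optional RNG seed.
#' @return Data.frame `embryo_id`, `sample_id`, `role` (`PB2`, `BLAST1`,
#'   `BLAST2`), `chrom`, `pos`, `ref_depth`, `alt_depth`.
#' @export
observe_cohort <- function(truth, catalog, panel, noise = noise_config(),
                           seg_config, seed = NULL) {
  stopifnot(inherits(noise, "noise_config"),
            inherits(seg_config, "segregation_config"))
  if (!is.null(seed)) set.seed(seed)
  loci <- panel_loci(panel, catalog)
  if (nrow(loci) == 0L) stop("panel covers no catalog variants")
  strain_a <- attr(catalog, "strain_a") %||% "B6"
  somatic_is_a <- seg_config$somatic_strain == strain_a
  sperm_is_a <- seg_config$sperm_strain == strain_a

  embryos <- unique(truth$embryo_id)
  m <- nrow(loci)
  tkey <- paste(truth$embryo_id, truth$chrom)
  roles <- c("PB2", "BLAST1", "BLAST2")
  out <- vector("list", length(roles))
  for (ri in seq_along(roles)) {
    role <- roles[ri]
    side_a <- if (role == "PB2") truth$pb2_a else truth$zyg_a
    side_b <- if (role == "PB2") truth$pb2_b else truth$zyg_b
    # chromatid copies -> allele copies, by background
    hom <- side_a + side_b
    if (seg_config$background == "HYBRID") {
      acop <- side_a; bcop <- side_b
    } else if (somatic_is_a) {
      acop <- hom; bcop <- 0L * hom
    } else {
      acop <- 0L * hom; bcop <- hom
    }
    if (seg_config$background == "FERTILIZED_INBRED" && role != "PB2") {
      if (sperm_is_a) acop <- acop + 1L else bcop <- bcop + 1L
    }
    idx <- match(paste(rep(embryos, each = m), rep(loci$chrom, length(embryos))),
                 tkey)
    depths <- emit_depths(acop[idx], bcop[idx], noise)
    out[[ri]] <- data.frame(
      embryo_id = rep(embryos, each = m),
      sample_id = paste0("E", rep(embryos, each = m), "_", role),
      role = role,
      chrom = rep(loci$chrom, length(embryos)),
      pos = rep(loci$pos, length(embryos)),
      ref_depth = depths$ref_depth, alt_depth = depths$alt_depth,
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, out)
  obs <- obs[order(obs$embryo_id, obs$role, match(obs$chrom, unique(loci$chrom)),
                   obs$pos), ]
  rownames(obs) <- NULL
  obs
}

#' Simulate a full trio cohort (truth + observations)
#'
#' @inheritParams observe_cohort
#' @param n_embryos Number of embryos.
#' @param chrom_map A [chromosome_map()].
#' @param seed RNG seed covering both truth and noise.
#' @return List with elements `truth`, `observations`, `meta`.
#' @export
simulate_cohort <- function(n_embryos, catalog, panel, seg_config,
                            noise = noise_config(),
                            chrom_map = mouse_chrom_map(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_cohort_truth(n_embryos, seg_config, chrom_map)
  obs <- observe_cohort(truth, catalog, panel, noise, seg_config)
  list(truth = truth, observations = obs,
       meta = list(n_embryos = n_embryos,
                   background = seg_config$background,
                   seed = seed,
                   retention_bias = seg_config$retention_bias,
                   fidelity_mix = seg_config$fidelity_mix))
}

#' Simulate the meiotic (1n2c) control
#'
#' Intact MII oocytes or transplanted spindles from an F1 hybrid carry a
#' haploid set of replicated chromosomes whose chromatids are recombinant
#' products of meiosis I. Each chromosome draws a Poisson number of
#' crossover breakpoints (uniform along its length); the two chromatids are
#' complementary strain mosaics sharing those breakpoints, and the second
#' division sends one to the pronucleus and one to the PB2. With a zero
#' crossover rate every chromosome is purely one strain and the PB2 carries
#' the complementary strain.
#'
#' @param n_oocytes Number of oocytes.
#' @param catalog A `consensus_catalog` (hybrid strain-diagnostic sites).
#' @param panel An `amplicon_panel`.
#' @param crossover_rate_per_chrom Mean crossovers per chromosome
#'   (default 1).
#' @param noise A [noise_config()].
#' @param chrom_map A [chromosome_map()].
#' @param seed Optional RNG seed.
#' @return List with `truth` (per oocyte x chromosome: `n_breakpoints`,
#'   `start_strain` of the pronucleus chromatid), `breakpoints` (long table
#'   of planted breakpoint positions) and `observations` (roles
#'   `PRONUCLEUS`, `PB2`).
#' @export
simulate_meiotic_control <- function(n_oocytes, catalog, panel,
                                     crossover_rate_per_chrom = 1,
                                     noise = noise_config(),
                                     chrom_map = mouse_chrom_map(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- panel_loci(panel, catalog)
  if (nrow(loci) == 0L) stop("panel covers no catalog variants")
  n_chrom <- nrow(chrom_map)
  grid <- expand.grid(chrom_i = seq_len(n_chrom), oocyte = seq_len(n_oocytes))
  k <- stats::rpois(nrow(grid), crossover_rate_per_chrom)
  start_a <- stats::runif(nrow(grid)) < 0.5   # pronucleus chromatid starts A?
  bp <- vector("list", nrow(grid))
  for (g in which(k > 0L)) {
    bp[[g]] <- sort(stats::runif(k[g], min = 1,
                                 max = chrom_map$length_bp[grid$chrom_i[g]]))
  }
  truth <- data.frame(oocyte_id = grid$oocyte,
                      chrom = chrom_map$chrom[grid$chrom_i],
                      n_breakpoints = k,
                      start_strain = ifelse(start_a, "A", "B"),
                      stringsAsFactors = FALSE)
  bp_tab <- data.frame(
    oocyte_id = rep(grid$oocyte, k),
    chrom = rep(chrom_map$chrom[grid$chrom_i], k),
    breakpoint = unlist(bp[k > 0L]),
    stringsAsFactors = FALSE)
  if (nrow(bp_tab) == 0L) {
    bp_tab <- data.frame(oocyte_id = integer(), chrom = character(),
                         breakpoint = numeric(), stringsAsFactors = FALSE)
  }

  m <- nrow(loci)
  gkey <- paste(grid$oocyte, chrom_map$chrom[grid$chrom_i])
  idx <- match(paste(rep(seq_len(n_oocytes), each = m),
                     rep(loci$chrom, n_oocytes)), gkey)
  locus_i <- rep(seq_len(m), n_oocytes)
  # strain at each locus of the pronucleus chromatid: start strain flipped
  # once per breakpoint left of the locus
  flips <- integer(length(idx))
  rows_by_group <- split(seq_along(idx), idx)
  for (g in which(k > 0L)) {
    sel <- rows_by_group[[as.character(g)]]
    if (!is.null(sel)) {
      flips[sel] <- findInterval(loci$pos[locus_i[sel]], bp[[g]])
    }
  }
  pro_is_a <- xor(start_a[idx], flips %% 2L == 1L)
  out <- vector("list", 2L)
  roles <- c("PRONUCLEUS", "PB2")
  for (ri in 1:2) {
    is_a <- if (ri == 1L) pro_is_a else !pro_is_a
    depths <- emit_depths(as.integer(is_a), as.integer(!is_a), noise)
    out[[ri]] <- data.frame(
      oocyte_id = rep(seq_len(n_oocytes), each = m),
      sample_id = paste0("O", rep(seq_len(n_oocytes), each = m), "_",
                         roles[ri]),
      role = roles[ri],
      chrom = rep(loci$chrom, n_oocytes),
      pos = rep(loci$pos, n_oocytes),
      ref_depth = depths$ref_depth, alt_depth = depths$alt_depth,
      stringsAsFactors = FALSE)
  }
  list(truth = truth, breakpoints = bp_tab, observations = do.call(rbind, out))
}

#' Write / read a simulated cohort directory
#'
#' Lossless plain-text round trip: `observations.tsv`, `truth.tsv` and
#' `meta.json` (which embeds the seed). Any missing file or malformed
#' schema is a named error.
#'
#' @param cohort List as returned by [simulate_cohort()].
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir`; `read_cohort()` the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$observations, file.path(dir, "observations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  need <- c("observations.tsv", "truth.tsv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("cohort file missing: ", file.path(dir, f))
    }
  }
  obs <- utils::read.delim(file.path(dir, "observations.tsv"),
                           stringsAsFactors = FALSE)
  obs_cols <- c("embryo_id", "sample_id", "role", "chrom", "pos",
                "ref_depth", "alt_depth")
  miss <- setdiff(obs_cols, names(obs))
  if (length(miss) > 0L) {
    stop("observations.tsv lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(obs$ref_depth)) || any(!is.finite(obs$alt_depth)) ||
      any(obs$ref_depth < 0) || any(obs$alt_depth < 0)) {
    stop("observations.tsv contains negative or non-finite depths")
  }
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  truth_cols <- c("embryo_id", "chrom", "proper", "pb2_a", "pb2_b",
                  "zyg_a", "zyg_b")
  miss <- setdiff(truth_cols, names(truth))
  if (length(miss) > 0L) {
    stop("truth.tsv lacks column(s): ", paste(miss, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  list(truth = truth, observations = obs, meta = meta)
}

#' Simulate per-strain callsets for consensus building
#'
#' Emulates independent variant-calling pipelines observing the same set of
#' truly strain-diagnostic sites: each source supports a site (strain A
#' homozygous reference, strain B homozygous alternate) with probability
#' `p_support`, reports it missing with probability `p_missing`, and
#' otherwise contradicts it with a heterozygous call in one strain.
#'
#' @param n_sites Number of true diagnostic sites (cluster anchors when
#'   `cluster_extra_lambda > 0`).
#' @param chrom_map A [chromosome_map()].
#' @param n_sources Number of callsets (default 3).
#' @param p_support,p_missing Per-source site probabilities.
#' @param cluster_extra_lambda Strain variants cluster locally; each anchor
#'   site gains a Poisson number of extra sites within a 120-bp
#'   neighborhood (default 0: uniform sites only).
#' @param seed Optional RNG seed.
#' @return List of [strain_callset()] objects.
#' @export
simulate_strain_callsets <- function(n_sites, chrom_map = mouse_chrom_map(),
                                     n_sources = 3L, p_support = 0.9,
                                     p_missing = 0.05,
                                     cluster_extra_lambda = 0,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p_support + p_missing > 1) stop("p_support + p_missing must be <= 1")
  ci <- sample.int(nrow(chrom_map), n_sites, replace = TRUE,
                   prob = chrom_map$length_bp)
  pos <- floor(stats::runif(n_sites, 1, chrom_map$length_bp[ci])) + 1L
  if (cluster_extra_lambda > 0) {
    k <- stats::rpois(n_sites, cluster_extra_lambda)
    off <- round(stats::runif(sum(k), -59, 59))
    ci <- c(ci, rep(ci, k))
    pos <- c(pos, pmax(1L, rep(pos, k) + as.integer(off)))
    pos <- pmin(pos, chrom_map$length_bp[ci])
  }
  key <- paste(chrom_map$chrom[ci], pos)
  keep <- !duplicated(key)
  ci <- ci[keep]; pos <- pos[keep]
  ord <- order(ci, pos)
  ci <- ci[ord]; pos <- pos[ord]
  n <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  lapply(seq_len(n_sources), function(s) {
    u <- stats::runif(n)
    gt_a <- rep("HOM_REF", n)
    gt_b <- rep("HOM_ALT", n)
    gt_a[u >= p_support & u < p_support + p_missing] <- "MISSING"
    contra <- u >= p_support + p_missing
    which_strain <- stats::runif(n) < 0.5
    gt_a[contra & which_strain] <- "HET"
    gt_b[contra & !which_strain] <- "HET"
    strain_callset(chrom_map$chrom[ci], pos, ref, alt, gt_a, gt_b,
                   source_name = paste0("caller", s))
  })
}
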