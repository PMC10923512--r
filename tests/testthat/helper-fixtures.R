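# Small fixtures built in code.

tiny_map <- function() chromosome_map(c("chr1", "chr2"), c(21e6, 14e6))

# a fully supported single-source catalog at the given sites
make_catalog <- function(chrom, pos, map,
                         ref = rep("A", length(pos)),
                         alt = rep("G", length(pos))) {
  cs <- strain_callset(chrom, pos, ref, alt,
                       rep("HOM_REF", length(pos)),
                       rep("HOM_ALT", length(pos)),
                       source_name = "fixture")
  build_consensus_catalog(list(cs), map, min_sources = 1L)
}

# random synthetic catalog on a small genome, mixing uniform and
# clustered sites so flank-purity rejections actually occur
random_catalog <- function(map, n_sites, seed) {
  set.seed(seed)
  ci <- sample.int(nrow(map), n_sites, replace = TRUE,
                   prob = map$length_bp)
  pos <- floor(runif(n_sites, 1, map$length_bp[ci])) + 1L
  n_clustered <- ceiling(n_sites / 3)
  anchors <- sample.int(n_sites, n_clustered, replace = TRUE)
  extra_ci <- ci[anchors]
  extra_pos <- pmax(1L, pos[anchors] +
                      as.integer(round(runif(n_clustered, -220, 220))))
  ci <- c(ci, extra_ci)
  pos <- pmin(c(pos, extra_pos), map$length_bp[ci])
  keep <- !duplicated(paste(ci, pos))
  make_catalog(map$chrom[ci[keep]], pos[keep], map)
}

# observation rows for one sample from explicit per-locus allele copies
obs_from_copies <- function(chrom, pos, a_cop, b_cop, depth = 250,
                            sample_id = "S1", role = "PB2",
                            embryo_id = 1L) {
  data.frame(embryo_id = embryo_id, sample_id = sample_id, role = role,
             chrom = chrom, pos = pos,
             ref_depth = ifelse(a_cop > 0,
                                round(depth * a_cop / pmax(1, a_cop + b_cop)),
                                0L),
             alt_depth = ifelse(b_cop > 0,
                                round(depth * b_cop / pmax(1, a_cop + b_cop)),
                                0L),
             stringsAsFactors = FALSE)
}
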