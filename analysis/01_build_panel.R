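#!/usr/bin/env Rscript
# Stage 1: consensus strain-diagnostic catalog and amplicon panel.
#
# Three simulated calling pipelines (playing the roles of independent
# callers plus a public strain callset) are intersected into a consensus
# catalog of B6/FVB-diagnostic SNVs, from which the targeted panel is
# designed: one window per 7-Mb interval, variant clusters within 120 bp,
# 80-bp variant-free flanks for primer binding.

suppressPackageStartupMessages(library(haploidtrace))

out_dir <- "results/analysis"
big_dir <- "scratch/analysis"   # large intermediates, regenerated by rerunning
dir.create(big_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20240101L

cm <- mouse_chrom_map()
message("genome frame: ", nrow(cm), " chromosome pairs, ",
        round(sum(cm$length_bp) / 1e9, 2), " Gb")

callsets <- simulate_strain_callsets(4000, cm, n_sources = 3L,
                                     cluster_extra_lambda = 8,
                                     seed = seed)
message("simulated ", length(callsets), " strain callsets of ",
        nrow(callsets[[1]]), " sites each")

catalog <- build_consensus_catalog(callsets, cm, min_sources = 2L)
message("consensus catalog: ", nrow(catalog), " strain-diagnostic variants ",
        "(sites supported by >= 2 of 3 sources, never contradicted)")
write_catalog_vcf(catalog, file.path(big_dir, "consensus_catalog.vcf"))

panel <- design_panel(catalog, cm)
viol <- validate_panel(panel, catalog, cm)
stopifnot(length(viol) == 0L)
amp_len <- panel$amplicon_end - panel$amplicon_start + 1
message(sprintf(
  "panel: %d regions (ceiling %d bins); %.1f variants/region (min %d, max %d); mean amplicon %.0f bp",
  nrow(panel), sum(ceiling(cm$length_bp / 7e6)), mean(panel$n_variants),
  min(panel$n_variants), max(panel$n_variants), mean(amp_len)))

write_panel_bed(panel, file.path(out_dir, "panel_amplicons.bed"))
write.table(as.data.frame(panel), file.path(out_dir, "panel_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(n_regions = nrow(panel),
                       n_catalog_variants = nrow(catalog),
                       mean_variants_per_region = mean(panel$n_variants),
                       mean_amplicon_bp = mean(amp_len)),
            file.path(out_dir, "panel_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote panel BED/TSV to ", out_dir, "; catalog VCF to ", big_dir)
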