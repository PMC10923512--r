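#!/usr/bin/env Rscript
# Stage 2: simulated study cohorts.
#
# Four cohorts mirror the study's arms at its sample sizes:
#   hybrid      63 SCNT embryos, random segregation (fidelity 0)
#   inbred      53 SCNT embryos, inbred-like fidelity mixture
#               (19% fully faithful, 81% at proper probability 0.63)
#   fertilized  14 inbred-FVB embryos fertilized with B6 sperm
#   meiotic     24 control oocytes (1n2c), 1 crossover/chromosome
# Depths follow the assay's 250x design mean with 0.1/allele WGA dropout.

suppressPackageStartupMessages(library(haploidtrace))

big_dir <- "scratch/analysis"
catalog <- read_catalog_vcf(file.path(big_dir, "consensus_catalog.vcf"))
cm <- mouse_chrom_map()
panel <- design_panel(catalog, cm)   # deterministic: same panel as stage 1
noise <- noise_config()              # 250x NB depth, 0.1 dropout

cohorts <- list(
  hybrid = list(n = 63L, sc = segregation_config("HYBRID"), seed = 211L),
  inbred = list(n = 53L,
                sc = segregation_config("INBRED",
                                        fidelity_mix = inbred_like_mix()),
                seed = 212L),
  fertilized = list(n = 14L,
                    sc = segregation_config("FERTILIZED_INBRED",
                                            fidelity_mix = inbred_like_mix()),
                    seed = 213L))

for (name in names(cohorts)) {
  cfg <- cohorts[[name]]
  coh <- simulate_cohort(cfg$n, catalog, panel, cfg$sc, noise, cm,
                         seed = cfg$seed)
  write_cohort(coh, file.path(big_dir, "cohorts", name))
  ts <- truth_summary(coh$truth)
  message(sprintf(
    "%-10s n=%2d  truth mean proper %.2f  complete haploidization %d/%d",
    name, cfg$n, mean(ts$n_proper), sum(ts$complete_haploidization), cfg$n))
}

mc <- simulate_meiotic_control(24, catalog, panel,
                               crossover_rate_per_chrom = 1,
                               noise = noise, chrom_map = cm, seed = 214L)
dir.create(file.path(big_dir, "cohorts", "meiotic"), showWarnings = FALSE,
           recursive = TRUE)
write.table(mc$observations,
            file.path(big_dir, "cohorts", "meiotic", "observations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mc$truth,
            file.path(big_dir, "cohorts", "meiotic", "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mc$breakpoints,
            file.path(big_dir, "cohorts", "meiotic", "breakpoints.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("meiotic    n=24  planted %.2f crossovers/chromosome",
                mean(mc$truth$n_breakpoints)))
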