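#!/usr/bin/env Rscript
# Stage 3: genotyping, trio QC and segregation classification.
#
# Per-locus genotypes are called under the assay's exclusion floors
# (homozygous < 12x, heterozygous < 24x treated as not amplified), pooled
# into per-chromosome origin profiles, and each trio (PB2 + two
# blastomeres) is checked for chromatid-accounting closure before its 20
# homolog pairs are classified as properly segregated, both-retained or
# both-extruded. The meiotic control is profiled for crossover switches.

suppressPackageStartupMessages(library(haploidtrace))

in_dir <- "results/analysis"
big_dir <- "scratch/analysis"
cm <- mouse_chrom_map()

for (name in c("hybrid", "inbred", "fertilized")) {
  coh <- read_cohort(file.path(big_dir, "cohorts", name))
  background <- coh$meta$background
  prof <- profile_cohort(coh$observations, cm)
  res <- classify_cohort(prof, background, cm)
  tab <- cohort_table(res$calls, nrow(cm))
  freq <- per_chromosome_frequency(res$calls, cm)
  bias <- nonsegregation_bias(res$calls)
  message(sprintf(
    "%-10s QC pass %d/%d | mean proper %.2f (median %d, mode %d) | mean retained %.1f | complete %.0f%% | retained:extruded %d:%d",
    name, sum(res$qc$qc_pass), nrow(res$qc), tab$stats$mean_proper,
    tab$stats$median_proper, tab$stats$mode_proper, tab$stats$mean_retained,
    100 * tab$stats$fraction_complete_haploidization,
    bias$both_retained, bias$both_extruded))
  write.table(tab$embryos,
              file.path(in_dir, paste0(name, "_embryo_summaries.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(freq,
              file.path(in_dir, paste0(name, "_per_chromosome.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$qc, file.path(in_dir, paste0(name, "_trio_qc.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# meiotic control: crossover switch detection
obs <- read.delim(file.path(big_dir, "cohorts", "meiotic", "observations.tsv"),
                  stringsAsFactors = FALSE)
prof <- profile_cohort(obs, cm)
truth <- read.delim(file.path(big_dir, "cohorts", "meiotic", "truth.tsv"),
                    stringsAsFactors = FALSE)
pro <- prof[prof$role == "PRONUCLEUS", ]
message(sprintf(
  "meiotic    planted %.2f bp/chrom, detected %.2f switches/chrom (panel-resolution detectability), %.0f%% chromosomes recombinant",
  mean(truth$n_breakpoints), mean(pro$switch_count),
  100 * mean(pro$content_state == "RECOMBINANT_SINGLE")))
write.table(as.data.frame(prof),
            file.path(in_dir, "meiotic_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
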