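#!/usr/bin/env Rscript
# Stage 4: Monte Carlo null and cohort statistics.
#
# The random-segregation null (each chromatid to PB2 or zygote with
# p = 0.5) is simulated at 100,000 embryos and checked against its
# analytic Binomial(20, 0.5) oracle; the simulated hybrid cohort is
# compared to the null and to the inbred cohort with the Wilcoxon rank sum
# test (continuity-corrected), and per-chromosome segregation frequency is
# correlated with chromosome length (Pearson).

suppressPackageStartupMessages(library(haploidtrace))

in_dir <- "results/analysis"
cm <- mouse_chrom_map()
seed <- 41L

nulls <- simulate_random_null(null_config(n_embryos = 1000L, n_reps = 100L,
                                          seed = seed))
tv <- total_variation(as.vector(nulls), binomial_proper_pmf(20L, 0.5))
message(sprintf(
  "Monte Carlo null: mean %.3f proper pairs (analytic 10), range %d-%d, TV vs Binomial(20,0.5) = %.4f",
  mean(nulls), min(nulls), max(nulls), tv))

hyb <- read.delim(file.path(in_dir, "hybrid_embryo_summaries.tsv"))
inb <- read.delim(file.path(in_dir, "inbred_embryo_summaries.tsv"))

w_null <- compare_observed_to_null(hyb$n_proper, nulls)
message(sprintf(
  "hybrid (n=%d, mean %.2f) vs random null: W = %.0f, p = %.3g -> %s",
  nrow(hyb), mean(hyb$n_proper), w_null$statistic, w_null$p_value,
  if (w_null$p_value < 0.05) "significant" else "not significant"))

w_ih <- wilcoxon_rank_sum(inb$n_proper, hyb$n_proper)
message(sprintf(
  "inbred (n=%d, mean %.2f) vs hybrid (n=%d, mean %.2f): W = %.0f, p = %.3g",
  nrow(inb), mean(inb$n_proper), nrow(hyb), mean(hyb$n_proper),
  w_ih$statistic, w_ih$p_value))

freq <- read.delim(file.path(in_dir, "hybrid_per_chromosome.tsv"))
r <- pearson_correlation(freq$length_bp, freq$proper_fraction)
message(sprintf(
  "chromosome length vs segregation frequency (hybrid): r = %.3f, p = %.3f",
  r$statistic, r$p_value))

report <- list(
  seed = seed,
  null = list(n = length(nulls), mean = mean(nulls),
              tv_vs_binomial = tv),
  hybrid_vs_null = list(W = w_null$statistic, p = w_null$p_value,
                        mean_hybrid = mean(hyb$n_proper),
                        mean_null = mean(nulls)),
  inbred_vs_hybrid = list(W = w_ih$statistic, p = w_ih$p_value,
                          mean_inbred = mean(inb$n_proper)),
  length_correlation = list(r = r$statistic, p = r$p_value))
jsonlite::write_json(report, file.path(in_dir, "stats_report.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(in_dir, "stats_report.json"))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("scratch", showWarnings = FALSE)
  library(ggplot2)
  df <- rbind(data.frame(group = "null", n_proper = as.vector(nulls)),
              data.frame(group = "hybrid", n_proper = hyb$n_proper),
              data.frame(group = "inbred", n_proper = inb$n_proper))
  gg <- ggplot(df, aes(n_proper, after_stat(density), fill = group)) +
    geom_histogram(binwidth = 1, position = "identity", alpha = 0.5) +
    labs(x = "properly segregated homolog pairs (of 20)",
         y = "density") + theme_minimal()
  ggsave("scratch/proper_pairs_distributions.png", gg,
         width = 7, height = 4, dpi = 150)
  message("wrote scratch/proper_pairs_distributions.png")
}
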