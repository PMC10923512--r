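#' End-to-end pipeline
#'
#' Runs every stage in order — consensus catalog, panel design, cohort
#' simulation, genotyping, segregation classification, Monte Carlo null and
#' cohort statistics — writing each stage's artifacts under one output
#' directory plus a checksummed manifest. Given the same seed and
#' configuration the run is fully reproducible (identical checksums).
#'
#' @param config Nested configuration list or path to a YAML file with
#'   optional sections `catalog` (`n_sites`, `n_sources`, `min_sources`,
#'   or `callset_vcfs`: paths of existing callset VCFs), `panel`
#'   (arguments of [panel_config()]), `cohort` (`n_embryos`, `background`,
#'   `retention_bias`, `fidelity`: `"random"` or `"inbred_like"`), `noise`
#'   (arguments of [noise_config()]), `genotype` (arguments of
#'   [genotype_config()]), and `null_model` (`n_reps`).
#' @param out_dir Output directory (created).
#' @param seed Integer seed funneled into every stochastic stage.
#' @param chrom_map A [chromosome_map()].
#' @return Invisibly, the manifest data.frame (`file`, `md5`), also
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L,
                         chrom_map = mouse_chrom_map()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- function(section, key, default) {
    val <- config[[section]][[key]]
    if (is.null(val)) default else val
  }

  # -- consensus catalog ----------------------------------------------
  catalog <- stage("consensus", {
    if (!is.null(config$catalog$callset_vcfs)) {
      callsets <- lapply(config$catalog$callset_vcfs, read_vcf_callset)
    } else {
      callsets <- simulate_strain_callsets(
        n_sites = cfg("catalog", "n_sites", 20000L),
        chrom_map = chrom_map,
        n_sources = cfg("catalog", "n_sources", 3L),
        seed = seed)
    }
    build_consensus_catalog(callsets, chrom_map,
                            min_sources = cfg("catalog", "min_sources", 2L))
  })
  write_catalog_vcf(catalog, file.path(out_dir, "consensus_catalog.vcf"))

  # -- panel design ---------------------------------------------------
  panel <- stage("design-panel", {
    pc <- do.call(panel_config, config$panel %||% list())
    p <- design_panel(catalog, chrom_map, pc)
    viol <- validate_panel(p, catalog, chrom_map)
    if (length(viol) > 0L) stop("panel validation failed: ", viol[1L])
    p
  })
  write_panel_bed(panel, file.path(out_dir, "panel_amplicons.bed"))
  utils::write.table(as.data.frame(panel),
                     file.path(out_dir, "panel_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- cohort simulation ----------------------------------------------
  cohort <- stage("simulate", {
    fid <- cfg("cohort", "fidelity", "random")
    mix <- if (identical(fid, "inbred_like")) inbred_like_mix() else
      data.frame(fraction = 1, phi = 0)
    sc <- segregation_config(
      background = cfg("cohort", "background", "HYBRID"),
      retention_bias = cfg("cohort", "retention_bias", 0.5),
      fidelity_mix = mix)
    nc <- do.call(noise_config, config$noise %||% list())
    simulate_cohort(cfg("cohort", "n_embryos", 63L), catalog, panel, sc,
                    nc, chrom_map, seed = seed + 1L)
  })
  write_cohort(cohort, file.path(out_dir, "cohort"))

  # -- genotyping + segregation ---------------------------------------
  profiles <- stage("genotype", {
    gc <- do.call(genotype_config, config$genotype %||% list())
    profile_cohort(cohort$observations, chrom_map, gc)
  })
  utils::write.table(as.data.frame(profiles),
                     file.path(out_dir, "chromosome_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seg <- stage("segregate", {
    background <- cfg("cohort", "background", "HYBRID")
    cl <- classify_cohort(profiles, background, chrom_map)
    tab <- cohort_table(cl$calls, nrow(chrom_map))
    list(cl = cl, tab = tab)
  })
  utils::write.table(seg$cl$qc, file.path(out_dir, "trio_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(seg$tab$embryos,
                     file.path(out_dir, "embryo_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  freq <- per_chromosome_frequency(seg$cl$calls, chrom_map)
  utils::write.table(freq, file.path(out_dir, "per_chromosome_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- null model + statistics ----------------------------------------
  stats_out <- stage("null-model", {
    nulls <- simulate_random_null(null_config(
      n_embryos = cfg("cohort", "n_embryos", 63L),
      n_pairs = nrow(chrom_map),
      n_reps = cfg("null_model", "n_reps", 100L), seed = seed + 2L))
    utils::write.table(data.frame(proper_count = as.vector(nulls)),
                       file.path(out_dir, "null_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    obs <- seg$tab$embryos$n_proper
    w <- compare_observed_to_null(obs, nulls)
    r <- if (nrow(freq) >= 3L && stats::sd(freq$proper_fraction) > 0) {
      pearson_correlation(freq$length_bp, freq$proper_fraction)
    } else list(statistic = NA_real_, p_value = NA_real_)
    bias <- nonsegregation_bias(seg$cl$calls)
    list(seed = seed,
         qc_pass = sum(seg$cl$qc$qc_pass), qc_fail = sum(!seg$cl$qc$qc_pass),
         cohort = seg$tab$stats,
         null_mean = mean(nulls),
         wilcoxon_vs_null = list(statistic = w$statistic,
                                 p_value = w$p_value, method = w$method),
         length_correlation = list(r = r$statistic, p_value = r$p_value),
         nonsegregation_bias = bias)
  })
  jsonlite::write_json(stats_out, file.path(out_dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- c("consensus_catalog.vcf", "panel_amplicons.bed",
             "panel_regions.tsv", file.path("cohort", "observations.tsv"),
             file.path("cohort", "truth.tsv"), file.path("cohort", "meta.json"),
             "chromosome_profiles.tsv", "trio_qc.tsv", "embryo_summaries.tsv",
             "per_chromosome_frequency.tsv", "null_distribution.tsv",
             "cohort_report.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
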