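test_that("depth floors exclude shallow loci from calling", {
  cfg <- genotype_config()
  # homozygous depth below 12x is not amplified
  expect_equal(call_locus_genotype(11L, 0L, cfg), "NO_CALL")
  expect_equal(call_locus_genotype(0L, 0L, cfg), "NO_CALL")
  expect_equal(call_locus_genotype(12L, 0L, cfg), "HOM_A")
  expect_equal(call_locus_genotype(0L, 12L, cfg), "HOM_B")
  # heterozygous total below 24x is not amplified
  expect_equal(call_locus_genotype(12L, 11L, cfg), "NO_CALL")
  expect_equal(call_locus_genotype(15L, 14L, cfg), "HET")
  expect_equal(call_locus_genotype(30L, 0L, cfg), "HOM_A")
  expect_error(call_locus_genotype(-1L, 5L, cfg), "non-negative")
})

test_that("vectorized calls agree with a scalar rule table on a depth grid", {
  cfg <- genotype_config()
  scalar_rule <- function(r, a) {
    tot <- r + a
    if (tot >= 24 && min(r, a) / tot >= 0.2) return("HET")
    if (r >= 12 && a / max(tot, 1) <= 0.05) return("HOM_A")
    if (a >= 12 && r / max(tot, 1) <= 0.05) return("HOM_B")
    "NO_CALL"
  }
  grid <- expand.grid(r = 0:40, a = 0:40)
  want <- mapply(scalar_rule, grid$r, grid$a)
  got <- call_locus_genotype(grid$r, grid$a, cfg)
  expect_equal(got, unname(want))
})

test_that("raising depth floors never converts NO_CALL into a call", {
  base <- genotype_config(min_hom_depth = 12L, min_het_depth = 24L)
  strict <- genotype_config(min_hom_depth = 20L, min_het_depth = 30L)
  grid <- expand.grid(r = 0:40, a = 0:40)
  c_base <- call_locus_genotype(grid$r, grid$a, base)
  c_strict <- call_locus_genotype(grid$r, grid$a, strict)
  expect_true(all(c_strict[c_base == "NO_CALL"] == "NO_CALL"))
})

test_that("chromosome origin follows the consensus/recombination rules", {
  pos <- seq(1e6, 10e6, by = 1e6)
  # 10x HOM_B -> single strain B
  p <- infer_chromosome_origin(pos, rep("HOM_B", 10))
  expect_equal(p$content_state, "SINGLE_B")
  expect_equal(p$switch_count, 0L)
  # alternating homozygous blocks -> recombinant single chromatid
  p <- infer_chromosome_origin(pos[1:6],
                               c("HOM_A", "HOM_A", "HOM_A",
                                 "HOM_B", "HOM_B", "HOM_B"))
  expect_equal(p$content_state, "RECOMBINANT_SINGLE")
  expect_equal(p$switch_count, 1L)
  # single isolated discordant locus absorbed as dropout/error
  p <- infer_chromosome_origin(pos[1:5],
                               c("HOM_A", "HOM_A", "HOM_B", "HOM_A", "HOM_A"))
  expect_equal(p$content_state, "SINGLE_A")
  expect_equal(p$switch_count, 0L)
  # two hets -> both homologs present
  p <- infer_chromosome_origin(pos[1:4],
                               c("HET", "HET", "HOM_A", "NO_CALL"))
  expect_equal(p$content_state, "BOTH")
  # too few informative loci -> absent
  p <- infer_chromosome_origin(pos[1:3],
                               c("NO_CALL", "NO_CALL", "HOM_A"))
  expect_equal(p$content_state, "ABSENT")
  # alternating singletons carry no block support -> ambiguous
  p <- infer_chromosome_origin(pos[1:4],
                               c("HOM_A", "HOM_B", "HOM_A", "HOM_B"))
  expect_equal(p$content_state, "AMBIGUOUS")
  expect_error(infer_chromosome_origin(c(2e6, 1e6), c("HOM_A", "HOM_A")),
               "increasing")
})

test_that("crossover intervals bracket the switch between blocks", {
  pos <- c(10e6, 20e6, 30e6, 37e6, 45e6, 50e6)
  p <- infer_chromosome_origin(pos, c(rep("HOM_A", 3), rep("HOM_B", 3)))
  iv <- detect_crossovers(p)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 30e6)
  expect_equal(iv$end, 37e6)
  expect_equal(iv$from_strain, "A")
  expect_equal(iv$to_strain, "B")
  # no intervals for non-recombinant content
  expect_equal(nrow(detect_crossovers(
    infer_chromosome_origin(pos, rep("HOM_A", 6)))), 0L)
  expect_equal(nrow(detect_crossovers(
    infer_chromosome_origin(pos, rep("HET", 6)))), 0L)
})

test_that("noise-free cohorts are profiled to their exact truth content", {
  cm <- tiny_map()
  cat_ <- make_catalog(rep(cm$chrom, each = 6),
                       as.integer(rep(seq(1e6, 6e6, by = 1e6), 2)), cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1.2e6L))
  sc <- segregation_config("HYBRID")
  coh <- simulate_cohort(30, cat_, p, sc, noiseless_config(), cm, seed = 10)
  prof <- profile_cohort(coh$observations, cm)
  truth <- coh$truth
  key <- paste(prof$embryo_id, prof$chrom)
  tkey <- paste(truth$embryo_id, truth$chrom)
  for (role in c("PB2", "BLAST1", "BLAST2")) {
    pr <- prof[prof$role == role, ]
    tr <- truth[match(paste(pr$embryo_id, pr$chrom), tkey), ]
    a <- if (role == "PB2") tr$pb2_a else tr$zyg_a
    b <- if (role == "PB2") tr$pb2_b else tr$zyg_b
    want <- ifelse(a + b == 0, "ABSENT",
                   ifelse(a + b == 2, "BOTH",
                          ifelse(a == 1, "SINGLE_A", "SINGLE_B")))
    expect_equal(pr$content_state, want)
  }
})

test_that("content accuracy stays >= 99% under 0.1 dropout with 8 loci", {
  # single-homolog chromosomes genotyped at 8 loci with per-allele dropout
  cm <- chromosome_map("chr1", 9e6)
  cat_ <- make_catalog(rep("chr1", 8), as.integer(seq(1e6, 8e6, by = 1e6)),
                       cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1.05e6L))
  sc <- segregation_config("HYBRID",
                           fidelity_mix = data.frame(fraction = 1, phi = 0))
  n <- 2500  # embryos x 1 chromosome x 3 samples = 7500 profiled chromosomes
  coh <- simulate_cohort(n, cat_, p, sc,
                         noise_config(allelic_dropout_rate = 0.1),
                         cm, seed = 11)
  prof <- profile_cohort(coh$observations, cm)
  truth <- coh$truth
  tkey <- paste(truth$embryo_id, truth$chrom)
  acc <- c()
  for (role in c("PB2", "BLAST1", "BLAST2")) {
    pr <- prof[prof$role == role, ]
    tr <- truth[match(paste(pr$embryo_id, pr$chrom), tkey), ]
    a <- if (role == "PB2") tr$pb2_a else tr$zyg_a
    b <- if (role == "PB2") tr$pb2_b else tr$zyg_b
    want <- ifelse(a + b == 0, "ABSENT",
                   ifelse(a + b == 2, "BOTH",
                          ifelse(a == 1, "SINGLE_A", "SINGLE_B")))
    acc <- c(acc, pr$content_state == want)
  }
  expect_gte(mean(acc), 0.99)
})
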