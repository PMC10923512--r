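test_that("segregation and noise configs validate their inputs", {
  expect_error(segregation_config(fidelity_mix = data.frame(fraction = 0.5,
                                                            phi = 1)),
               "sum to 1")
  expect_error(segregation_config(retention_bias = 1.2), "\\[0, 1\\]")
  expect_error(noise_config(mean_depth = -1), "positive")
  expect_error(noise_config(allelic_dropout_rate = 2), "\\[0, 1\\]")
  expect_equal(fidelity_for_proper(0.63), 0.26)
  expect_equal(fidelity_for_proper(c(0.5, 1)), c(0, 1))
})

test_that("full fidelity gives all-proper truths with exact chromatid conservation", {
  cm <- tiny_map()
  sc <- segregation_config("HYBRID",
                           fidelity_mix = data.frame(fraction = 1, phi = 1))
  truth <- simulate_cohort_truth(50, sc, cm, seed = 1)
  expect_true(all(truth$proper))
  # every chromatid appears exactly once across PB2 + zygote
  expect_true(all(truth$pb2_a + truth$zyg_a == 1L))
  expect_true(all(truth$pb2_b + truth$zyg_b == 1L))
  ts <- truth_summary(truth)
  expect_true(all(ts$n_proper == 2L))
  expect_true(all(ts$complete_haploidization))
})

test_that("zero fidelity is the pure random model with mean n_pairs/2", {
  cm <- mouse_chrom_map()
  sc <- segregation_config("HYBRID",
                           fidelity_mix = data.frame(fraction = 1, phi = 0))
  truth <- simulate_cohort_truth(10000, sc, cm, seed = 2)
  ts <- truth_summary(truth)
  # analytic mean 20 * 0.5 = 10, SE = sqrt(20*0.25/10000) ~ 0.022
  expect_lt(abs(mean(ts$n_proper) - 10), 0.1)
  # conservation holds in every row regardless of outcome
  expect_true(all(truth$pb2_a + truth$zyg_a == 1L))
  expect_true(all(truth$pb2_b + truth$zyg_b == 1L))
})

test_that("retention_bias = 1 sends every nonsegregating pair to the zygote", {
  cm <- tiny_map()
  sc <- segregation_config("HYBRID", retention_bias = 1,
                           fidelity_mix = data.frame(fraction = 1, phi = 0))
  truth <- simulate_cohort_truth(500, sc, cm, seed = 3)
  ns <- truth[!truth$proper, ]
  expect_gt(nrow(ns), 0)
  expect_true(all(ns$zyg_a == 1L & ns$zyg_b == 1L))
})

test_that("noise-free hybrid observations encode the carried alleles exactly", {
  cm <- tiny_map()
  cat_ <- make_catalog(rep("chr1", 4), c(1000L, 1100L, 2000L, 2100L), cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1e6L,
                                           flank_bp = 10L))
  sc <- segregation_config("HYBRID",
                           fidelity_mix = data.frame(fraction = 1, phi = 1))
  coh <- simulate_cohort(3, cat_, p, sc, noiseless_config(100), cm, seed = 4)
  obs <- coh$observations
  # blastomeres carry identical zygote content: identical noise-free depths
  b1 <- obs[obs$role == "BLAST1", ]
  b2 <- obs[obs$role == "BLAST2", ]
  expect_equal(b1$ref_depth, b2$ref_depth)
  expect_equal(b1$alt_depth, b2$alt_depth)
  # proper pairs: single homolog per side, so pure depth on one allele
  expect_true(all(b1$ref_depth + b1$alt_depth == 100L))
  expect_true(all(b1$ref_depth == 0L | b1$alt_depth == 0L))
})

test_that("meiotic control without crossovers gives complementary pure strains", {
  cm <- tiny_map()
  cat_ <- make_catalog(rep(cm$chrom, each = 4),
                       as.integer(rep(c(1e5, 2e5, 3e5, 4e5), times = 2)), cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1e6L))
  mc <- simulate_meiotic_control(10, cat_, p, crossover_rate_per_chrom = 0,
                                 noise = noiseless_config(100),
                                 chrom_map = cm, seed = 5)
  expect_true(all(mc$truth$n_breakpoints == 0L))
  obs <- mc$observations
  key <- paste(obs$oocyte_id, obs$chrom)
  for (k in unique(key)) {
    pro <- obs[key == k & obs$role == "PRONUCLEUS", ]
    pb2 <- obs[key == k & obs$role == "PB2", ]
    pro_a <- all(pro$ref_depth > 0) && all(pro$alt_depth == 0)
    pro_b <- all(pro$alt_depth > 0) && all(pro$ref_depth == 0)
    expect_true(pro_a || pro_b)  # purely one strain
    # PB2 carries the complementary strain
    if (pro_a) expect_true(all(pb2$ref_depth == 0))
    if (pro_b) expect_true(all(pb2$alt_depth == 0))
  }
})

test_that("planted crossovers flip locus strains at the recorded breakpoints", {
  cm <- chromosome_map("chr1", 10e6)
  cat_ <- make_catalog(rep("chr1", 10), as.integer(seq(5e5, 9.5e6, by = 1e6)),
                       cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1e6L))
  mc <- simulate_meiotic_control(50, cat_, p, crossover_rate_per_chrom = 2,
                                 noise = noiseless_config(100),
                                 chrom_map = cm, seed = 6)
  obs <- mc$observations[mc$observations$role == "PRONUCLEUS", ]
  for (oid in unique(obs$oocyte_id)) {
    o <- obs[obs$oocyte_id == oid, ]
    o <- o[order(o$pos), ]
    tr <- mc$truth[mc$truth$oocyte_id == oid, ]
    bp <- mc$breakpoints$breakpoint[mc$breakpoints$oocyte_id == oid]
    want <- mosaic_strain(o$pos, bp, tr$start_strain)
    got <- ifelse(o$ref_depth > 0, "A", "B")
    expect_equal(got, want)
  }
})

test_that("cohorts round-trip losslessly through a directory and bad input is named", {
  cm <- tiny_map()
  cat_ <- make_catalog(rep("chr1", 2), c(1000L, 1100L), cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1e6L))
  sc <- segregation_config("HYBRID")
  coh <- simulate_cohort(5, cat_, p, sc, noise_config(), cm, seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$observations, coh$observations)
  expect_equal(back$truth[, c("embryo_id", "chrom", "proper")],
               coh$truth[, c("embryo_id", "chrom", "proper")])
  expect_equal(back$meta$seed, 8)

  file.remove(file.path(dir, "truth.tsv"))
  expect_error(read_cohort(dir), "truth.tsv")

  # schema violation: negative depth
  coh2 <- coh
  coh2$observations$ref_depth[1] <- -5L
  dir2 <- withr::local_tempdir()
  write_cohort(coh2, dir2)
  expect_error(read_cohort(dir2), "negative")

  # empty cohort is fine
  coh3 <- coh
  coh3$observations <- coh$observations[0, ]
  coh3$truth <- coh$truth[0, ]
  dir3 <- withr::local_tempdir()
  write_cohort(coh3, dir3)
  expect_equal(nrow(read_cohort(dir3)$observations), 0L)
})
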