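make_profiles <- function(states, cm, embryo_id = 1L) {
  # states: list(PB2 = c(...), BLAST1 = ..., BLAST2 = ...) per chromosome
  do.call(rbind, lapply(names(states), function(role) {
    data.frame(sample_id = paste0("E", embryo_id, "_", role), role = role,
               embryo_id = embryo_id, chrom = cm$chrom,
               content_state = states[[role]], switch_count = 0L,
               informative = 5L, n_het = 0L, stringsAsFactors = FALSE)
  }))
}

test_that("a clean proper trio passes QC and a degraded PB2 fails with reasons", {
  cm <- tiny_map()
  ok <- make_profiles(list(PB2 = c("SINGLE_A", "SINGLE_B"),
                           BLAST1 = c("SINGLE_B", "SINGLE_A"),
                           BLAST2 = c("SINGLE_B", "SINGLE_A")), cm)
  q <- qc_trio(ok, "HYBRID", cm)
  expect_true(q$pass)
  expect_length(q$reasons, 0L)

  degraded <- make_profiles(list(PB2 = c("ABSENT", "ABSENT"),
                                 BLAST1 = c("SINGLE_B", "SINGLE_A"),
                                 BLAST2 = c("SINGLE_B", "SINGLE_A")), cm)
  q <- qc_trio(degraded, "HYBRID", cm)
  expect_false(q$pass)
  expect_match(q$reasons, "accounting open on 2 chromosome")

  disc <- make_profiles(list(PB2 = c("SINGLE_A", "SINGLE_B"),
                             BLAST1 = c("SINGLE_B", "SINGLE_A"),
                             BLAST2 = c("SINGLE_B", "SINGLE_B")), cm)
  q <- qc_trio(disc, "HYBRID", cm)
  expect_false(q$pass)
  expect_match(paste(q$reasons, collapse = " "), "discordance at chr2")

  expect_error(qc_trio(ok[ok$role != "PB2", ], "HYBRID", cm), "PB2")
})

test_that("hybrid pair classification follows the truth table", {
  cl <- classify_segregation_pair(
    rep("chr1", 6),
    c("SINGLE_B", "SINGLE_A", "BOTH", "ABSENT", "SINGLE_A", "ABSENT"),
    c("SINGLE_A", "SINGLE_B", "ABSENT", "BOTH", "SINGLE_A", "ABSENT"),
    "HYBRID")
  expect_equal(cl$verdict,
               c("PROPER", "PROPER", "BOTH_EXTRUDED", "BOTH_RETAINED",
                 "UNDETERMINED", "UNDETERMINED"))
  expect_error(classify_segregation_pair("chr1", "BOTH", "ABSENT", "MIXED"),
               "unknown background")
})

test_that("inbred classification uses presence only; fertilized needs the sperm het", {
  cl <- classify_segregation_pair(
    rep("chr1", 3),
    c("SINGLE_B", "SINGLE_B", "ABSENT"),
    c("SINGLE_B", "ABSENT", "SINGLE_B"),
    "INBRED")
  expect_equal(cl$verdict, c("PROPER", "BOTH_EXTRUDED", "BOTH_RETAINED"))

  # FVB somatic (strain B) x B6 sperm (strain A)
  cl <- classify_segregation_pair(
    rep("chr1", 4),
    c("SINGLE_B", "ABSENT", "SINGLE_B", "SINGLE_A"),
    c("BOTH", "BOTH", "SINGLE_A", "BOTH"),
    "FERTILIZED_INBRED", somatic_strain = "B", sperm_strain = "A")
  expect_equal(cl$verdict,
               c("PROPER", "BOTH_RETAINED", "BOTH_EXTRUDED", "UNDETERMINED"))
})

test_that("embryo summaries do the chromatid arithmetic", {
  calls <- data.frame(chrom = paste0("chr", 1:20),
                      verdict = c(rep("PROPER", 10),
                                  rep("BOTH_RETAINED", 5),
                                  rep("BOTH_EXTRUDED", 5)))
  s <- summarize_embryo(calls, 20L, 7L)
  expect_equal(s$n_proper, 10L)
  expect_equal(s$n_retained_chromatids, 20L)  # 10 proper + 2*5 retained
  expect_false(s$complete_haploidization)

  all_proper <- data.frame(chrom = paste0("chr", 1:20),
                           verdict = rep("PROPER", 20))
  s <- summarize_embryo(all_proper, 20L)
  expect_equal(s$n_proper, 20L)
  expect_equal(s$n_retained_chromatids, 20L)
  expect_true(s$complete_haploidization)

  expect_error(summarize_embryo(calls[1:7, ], 20L), "expected 20")
})

test_that("noise-free end-to-end cohorts recover every per-pair verdict", {
  cm <- tiny_map()
  cat_ <- make_catalog(rep(cm$chrom, each = 6),
                       as.integer(rep(seq(1e6, 6e6, by = 1e6), 2)), cm)
  p <- design_panel(cat_, cm, panel_config(interval_bp = 1.2e6L))
  sc <- segregation_config("HYBRID")
  coh <- simulate_cohort(40, cat_, p, sc, noiseless_config(), cm, seed = 21)
  prof <- profile_cohort(coh$observations, cm)
  res <- classify_cohort(prof, "HYBRID", cm)
  expect_true(all(res$qc$qc_pass))
  truth <- coh$truth
  m <- merge(res$calls, truth, by = c("embryo_id", "chrom"))
  want <- ifelse(m$proper, "PROPER",
                 ifelse(m$zyg_a + m$zyg_b == 2L, "BOTH_RETAINED",
                        "BOTH_EXTRUDED"))
  expect_equal(m$verdict, want)
  # accounting conservation: 2 chromatids per pair across the trio
  s <- cohort_table(res$calls, nrow(cm))
  pb2_chromatids <- with(truth, tapply(pb2_a + pb2_b, embryo_id, sum))
  pb2_chromatids <- pb2_chromatids[as.character(s$embryos$embryo_id)]
  expect_equal(s$embryos$n_retained_chromatids + as.integer(pb2_chromatids),
               rep(2L * nrow(cm), 40))
})

test_that("per-chromosome frequencies and retention bias recover generator settings", {
  cm <- mouse_chrom_map()
  sc <- segregation_config("HYBRID", retention_bias = 0.7,
                           fidelity_mix = data.frame(fraction = 1, phi = 0))
  truth <- simulate_cohort_truth(8000, sc, cm, seed = 22)
  # classification straight from truth states (exact observation)
  calls <- data.frame(
    embryo_id = truth$embryo_id, chrom = truth$chrom,
    verdict = ifelse(truth$proper, "PROPER",
                     ifelse(truth$zyg_a + truth$zyg_b == 2L,
                            "BOTH_RETAINED", "BOTH_EXTRUDED")))
  freq <- per_chromosome_frequency(calls, cm)
  # every chromosome's proper fraction ~ 0.5 (binomial SE ~ 0.0056)
  expect_true(all(abs(freq$proper_fraction - 0.5) < 3.5 * 0.0056))
  bias <- nonsegregation_bias(calls)
  p_hat <- bias$retained_fraction
  se <- sqrt(0.7 * 0.3 / (bias$both_retained + bias$both_extruded))
  expect_lt(abs(p_hat - 0.7), 3 * se)
})

test_that("an all-proper cohort reports the no-nonsegregation sentinel", {
  calls <- data.frame(embryo_id = 1L, chrom = paste0("chr", 1:20),
                      verdict = "PROPER")
  b <- nonsegregation_bias(calls)
  expect_true(b$no_nonsegregation)
  expect_true(is.na(b$ratio))
  expect_error(nonsegregation_bias(calls[0, ]), "empty cohort")
  expect_error(per_chromosome_frequency(calls[0, ]), "empty cohort")
})
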