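test_that("chromosome map enforces its frame invariants", {
  cm <- tiny_map()
  expect_equal(attr(cm, "n_pairs"), 2L)
  expect_equal(attr(cm, "n_chromatids"), 4L)
  expect_error(chromosome_map(c("chr1", "chr1"), c(10, 20)), "unique")
  expect_error(chromosome_map("chr1", 0), "positive")
  mouse <- mouse_chrom_map()
  expect_equal(attr(mouse, "n_pairs"), 20L)
  expect_equal(attr(mouse, "n_chromatids"), 40L)
  expect_false("chrY" %in% mouse$chrom)
})

test_that("chromosome map round-trips through TSV", {
  cm <- tiny_map()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chrom_map(cm, path)
  expect_equal(as.data.frame(read_chrom_map(path)), as.data.frame(cm))
})

test_that("single supporting source retains a site at min_sources = 1", {
  cm <- tiny_map()
  cs <- strain_callset("chr1", 100L, "A", "G", "HOM_REF", "HOM_ALT")
  cat_ <- build_consensus_catalog(list(cs), cm, min_sources = 1L)
  expect_equal(nrow(cat_), 1L)
  expect_equal(cat_$pos, 100L)
})

test_that("a heterozygous call in any source drops the site", {
  cm <- tiny_map()
  s1 <- strain_callset("chr1", c(100L, 200L), c("A", "C"), c("G", "T"),
                       c("HOM_REF", "HOM_REF"), c("HOM_ALT", "HOM_ALT"),
                       source_name = "s1")
  s2 <- strain_callset("chr1", c(100L, 200L), c("A", "C"), c("G", "T"),
                       c("HOM_REF", "HOM_REF"), c("HET", "HOM_ALT"),
                       source_name = "s2")
  cat_ <- build_consensus_catalog(list(s1, s2), cm, min_sources = 2L)
  expect_equal(cat_$pos, 200L)
})

test_that("three sources agreeing at 5 of 8 sites yield exactly those 5", {
  cm <- tiny_map()
  pos <- seq(1000L, 8000L, by = 1000L)
  base <- function(gt_a, gt_b, name) {
    strain_callset(rep("chr1", 8), pos, rep("A", 8), rep("G", 8),
                   gt_a, gt_b, source_name = name)
  }
  # sites 1-5 cleanly supported everywhere; 6 contradicted in s3 (het A),
  # 7 supported only once (missing elsewhere), 8 opposite homozygote in s2
  s1 <- base(rep("HOM_REF", 8), rep("HOM_ALT", 8), "s1")
  s2 <- base(c(rep("HOM_REF", 7), "HOM_ALT"),
             c(rep("HOM_ALT", 6), "MISSING", "HOM_ALT"), "s2")
  s3 <- base(c(rep("HOM_REF", 5), "HET", "HOM_REF", "HOM_REF"),
             c(rep("HOM_ALT", 6), "MISSING", "HOM_ALT"), "s3")
  cat_ <- build_consensus_catalog(list(s1, s2, s3), cm, min_sources = 2L)
  expect_equal(cat_$pos, pos[1:5])
  expect_equal(as.data.frame(cat_)[, c("chrom", "pos")],
               oracle_consensus(list(s1, s2, s3), 2L),
               ignore_attr = TRUE)
})

test_that("consensus equals the brute-force rule on random instances", {
  cm <- tiny_map()
  set.seed(11)
  for (rep in 1:20) {
    n_src <- sample(1:3, 1)
    n_sites <- sample(5:50, 1)
    pos <- sort(sample.int(1e6, n_sites))
    callsets <- lapply(seq_len(n_src), function(s) {
      strain_callset(rep("chr1", n_sites), pos, rep("A", n_sites),
                     rep("G", n_sites),
                     sample(c("HOM_REF", "HOM_ALT", "HET", "MISSING"),
                            n_sites, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
                     sample(c("HOM_ALT", "HOM_REF", "HET", "MISSING"),
                            n_sites, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
                     source_name = paste0("s", s))
    })
    ms <- sample.int(n_src, 1)
    got <- build_consensus_catalog(callsets, cm, ms)
    want <- oracle_consensus(callsets, ms)
    expect_equal(got$pos, want$pos)
  }
})

test_that("consensus is monotone in concordant and contradicting sources", {
  cm <- tiny_map()
  pos <- c(100L, 500L, 900L)
  support <- strain_callset(rep("chr1", 3), pos, rep("A", 3), rep("G", 3),
                            rep("HOM_REF", 3), rep("HOM_ALT", 3))
  base <- build_consensus_catalog(list(support), cm, 1L)
  more <- build_consensus_catalog(list(support, support), cm, 1L)
  expect_true(all(base$pos %in% more$pos))  # concordant source never removes
  contra <- strain_callset("chr1", 500L, "A", "G", "HET", "HOM_ALT")
  fewer <- build_consensus_catalog(list(support, contra), cm, 1L)
  expect_false(500L %in% fewer$pos)         # contradiction always removes
  expect_true(all(c(100L, 900L) %in% fewer$pos))
})

test_that("unknown chromosomes and zero callsets are rejected with diagnostics", {
  cm <- tiny_map()
  bad <- strain_callset("chr9", 100L, "A", "G", "HOM_REF", "HOM_ALT")
  expect_error(build_consensus_catalog(list(bad), cm, 1L), "chr9")
  expect_error(build_consensus_catalog(list(), cm, 1L), "at least one")
})

test_that("catalog VCF write/read round-trips and skips non-SNVs", {
  cm <- tiny_map()
  cat_ <- make_catalog(rep("chr1", 10), seq(1000L, 10000L, by = 1000L), cm)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_catalog_vcf(cat_, path)
  back <- read_catalog_vcf(path)
  expect_equal(as.data.frame(back)[, c("chrom", "pos", "ref", "alt")],
               as.data.frame(cat_)[, c("chrom", "pos", "ref", "alt")])

  # hand-built VCF with one multi-allelic record among 5
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "B6", "FVB"), collapse = "\t"),
           "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1",
           "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t1/1",
           "chr1\t300\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
           "chr1\t400\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t1/1",
           "chr1\t500\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t1/1")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path2)
  expect_message(cs <- read_vcf_callset(path2), "skipped 1")
  expect_equal(nrow(cs), 4L)
  expect_equal(attr(cs, "n_skipped"), 1L)
  expect_equal(cs$gt_b[cs$pos == 300L], "HET")
  expect_equal(cs$gt_a[cs$pos == 500L], "MISSING")

  # empty body
  path3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf[1:3], path3)
  expect_equal(nrow(read_vcf_callset(path3)), 0L)
})
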