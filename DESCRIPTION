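Package: haploidtrace
Title: Homologous Chromosome Segregation Analysis After Premature Cell
    Division of Somatic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for inferring homologous-chromosome segregation after
    premature cell division of nonreplicated (2n2c) somatic genomes in
    nuclear-transfer oocytes. Builds a consensus catalog of strain-diagnostic
    variants from per-strain callsets, designs a targeted amplicon panel
    tiled along each chromosome, simulates trio cohorts (second polar body
    plus two blastomeres) with whole-genome-amplification allelic dropout
    and amplicon-depth noise, calls single-cell genotypes under depth-floor
    exclusion rules, classifies per-pair segregation (proper versus both
    homologs retained or extruded), detects crossover breakpoints from
    alternating homozygosity blocks, and compares cohorts against a Monte
    Carlo random-segregation null with its analytic binomial oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
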