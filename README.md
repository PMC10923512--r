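# haploidtrace

Chromosome segregation analysis for **premature cell division of somatic
genomes**. When a nonreplicated G0/G1 somatic nucleus (2n2c) is placed
into an enucleated metaphase-II mouse oocyte, the premature spindle
partitions the 40 single-chromatid chromosomes between a second polar
body (PB2) and the zygote. `haploidtrace` reconstructs, per homolog pair,
whether that partition was *proper* (one homolog to each side — the
reductional, meiosis-I-like outcome) from targeted amplicon sequencing of
the trio: the PB2 plus the two sister blastomeres, which jointly account
for all 40 chromatids.

The package implements the full computational chain, each step a tested,
reusable function:

1. **Consensus catalog** (`build_consensus_catalog`) — intersect
   per-strain variant callsets into strain-diagnostic biallelic SNVs
   (B6 homozygous-reference / FVB homozygous-alternate in ≥
   `min_sources` callsets, never contradicted).
2. **Panel design** (`design_panel`) — tile each chromosome into 7-Mb
   bins and pick per bin one variant cluster spanning ≤ 120 bp with
   80-bp variant-free flanks (primer sites); deterministic tie-break,
   verified against a brute-force oracle.
3. **Cohort simulation** (`simulate_cohort`,
   `simulate_meiotic_control`) — truth-level chromatid partitions under
   an embryo-level pairing-fidelity mixture, observed as per-variant
   allele depths with negative-binomial coverage (mean 250×), per-allele
   WGA dropout and per-base error.
4. **Genotype and origin inference** (`call_locus_genotype`,
   `profile_cohort`, `detect_crossovers`) — depth-floor exclusions
   (hom < 12×, het < 24× treated as not amplified), chromosome-level
   content consensus, crossover-block detection.
5. **Trio QC and classification** (`classify_cohort`,
   `cohort_table`) — chromatid-accounting closure across the trio, then
   per-pair verdicts: proper / both retained / both extruded.
6. **Null model and statistics** (`simulate_random_null`,
   `binomial_proper_pmf`, `wilcoxon_rank_sum`,
   `pearson_correlation`) — Monte Carlo random segregation with its
   analytic binomial oracle and the cohort comparisons.

## The null model

Under random segregation each chromatid of a pair independently lands in
the zygote with probability p = 0.5, so a pair segregates properly with
probability 2p(1−p) = 0.5 and the per-embryo count of proper pairs is
Binomial(20, 0.5):

```
E[# proper pairs] = 20 · 2p(1−p) = 10   at p = 0.5
```

A hybrid (B6×FVB) cohort matching this expectation indicates random
partition; an inbred cohort sitting significantly above it indicates
homology-driven, meiosis-I-like segregation.

## Worked example

The `analysis/` scripts run the whole study-scale workflow
(`01_build_panel.R` → `04_null_model_stats.R`; small tables under
`results/analysis/`, large intermediates under `scratch/`). Their actual
output:

```
consensus catalog: 29251 strain-diagnostic variants (sites supported by >= 2 of 3 sources, never contradicted)
panel: 383 regions (ceiling 385 bins); 11.3 variants/region (min 7, max 16); mean amplicon 256 bp

hybrid     QC pass 63/63 | mean proper 10.30 (median 10, mode 10) | mean retained 19.8 | complete 0%  | retained:extruded 300:311
inbred     QC pass 53/53 | mean proper 14.00 (median 13, mode 20) | mean retained 20.2 | complete 21% | retained:extruded 163:155
fertilized QC pass 14/14 | mean proper 13.00 (median 13, mode 10) | mean retained 20.0 | complete 14% | retained:extruded 49:49
meiotic    planted 0.94 bp/chrom, detected 0.86 switches/chrom (panel-resolution detectability), 61% chromosomes recombinant

Monte Carlo null: mean 10.008 proper pairs (analytic 10), range 1-19, TV vs Binomial(20,0.5) = 0.0057
hybrid (n=63, mean 10.30) vs random null: W = 3407750, p = 0.256 -> not significant
inbred (n=53, mean 14.00) vs hybrid (n=63, mean 10.30): W = 2672, p = 2.26e-08
chromosome length vs segregation frequency (hybrid): r = 0.380, p = 0.098
```

Reading it: the simulated hybrid cohort is statistically
indistinguishable from the random null (mean ≈ 10 of 20 pairs proper),
the inbred cohort segregates far better (mean 14, 21% of embryos fully
haploidized, Wilcoxon p ≈ 10⁻⁸ vs hybrid), retention vs extrusion of
nonsegregating pairs is balanced at the generator's 0.5 setting, and
chromosome length does not predict segregation frequency. The meiotic
control shows the alternating-strain crossover blocks that somatic
cohorts must lack — and the somatic cohorts report zero recombinant
chromosomes.

A minimal interactive session:

```r
library(haploidtrace)
cm   <- mouse_chrom_map()                       # 20 pairs, 40 chromatids
counts <- simulate_random_null(null_config(n_embryos = 1000L,
                                           n_reps = 100L, seed = 1L))
mean(counts)                                    # 10.0041
total_variation(counts, binomial_proper_pmf(20, 0.5))  # 0.0056
enumerate_pair_assignments(0.5)                 # the 4 pole assignments
#>   chromatid_a chromatid_b probability proper
#> 1      ZYGOTE      ZYGOTE        0.25  FALSE
#> 2         PB2      ZYGOTE        0.25   TRUE
#> 3      ZYGOTE         PB2        0.25   TRUE
#> 4         PB2         PB2        0.25  FALSE
```

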