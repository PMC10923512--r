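---
title: "Inferring homolog segregation after premature division of somatic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring homolog segregation after premature division of somatic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploidtrace)
```

## The inference problem

When a nonreplicated G0/G1 somatic nucleus (2n2c: 2n chromosomes, each a
single chromatid) is transplanted into an enucleated metaphase-II oocyte,
the residual M-phase activity builds a premature spindle and the ensuing
division partitions the 40 mouse chromatids between a second polar body
(PB2) and the zygote. The central question is *how* homolog pairs
partition: a pair segregates **properly** when one homolog goes to each
side (a reductional, meiosis-I-like outcome); otherwise both homologs are
retained in the zygote or both extruded into the PB2.

Because the PB2 and the two sister blastomeres of one embryo (the *trio*)
jointly carry all 40 chromatids, sequencing all three samples lets every
pair's fate be reconstructed — provided the assay can tell the two
homologs apart. In an F1 hybrid (B6 × FVB) the homologs differ at millions
of strain-diagnostic SNVs; in inbred backgrounds they are essentially
identical and only presence/absence is observable.

`haploidtrace` implements the complete computational chain: consensus
variant catalog → amplicon panel design → single-cell genotype calling →
chromosome-origin inference → trio QC and segregation classification →
Monte Carlo null comparison, plus a synthetic-data generator that stands
in for the raw sequencing.

## Consensus catalog and panel design

Strain-diagnostic sites are taken as the intersection of independent
callsets: a site is kept iff it is homozygous-reference in the strain-A
sample and homozygous-alternate in the strain-B sample in at least
`min_sources` callsets and never contradicted (heterozygous or opposite
homozygote, or disagreeing alleles) anywhere. `MISSING` calls neither
support nor contradict. The required arity is exposed as `min_sources`
(default 2 of 3) because intersection-of-three and any-two are both
defensible readings of a three-way comparison; the rule's monotonicity
(adding a concordant source never removes a site, a contradicting source
always does) is property-tested.

The panel tiles each chromosome into consecutive 7-Mb bins anchored at
position 1, so target counts scale with chromosome length; the female
frame (19 autosomes + X) never includes Y. Within a bin, candidate
windows are *maximal variant clusters*: from each variant, the run of
catalog variants spanning at most 120 bp. A candidate is admissible when
its two 80-bp flanks — the prospective primer binding sites — contain no
catalog variant at all (checked against the whole catalog, not just the
bin) and its amplicon does not overlap the previously selected region.
Design choices that the constraints alone do not fix:

* **Tie-break**: most variants, then shortest span, then leftmost start.
  Deterministic, so identical inputs give identical panels.
* **`min_variants_per_window = 2` with fallback to 1**: windows should
  carry multiple diagnostic variants, but a bin whose only admissible
  windows are single-variant still yields a region — which is why
  per-region variant counts can reach down to 1.
* **Bin anchoring at position 1**: the simplest fixed tiling; nothing in
  the design depends on the anchor beyond region placement.

The designer is verified against a brute-force oracle (exhaustive
candidate enumeration with the same tie-break) on 100 random catalogs,
and `validate_panel()` re-checks every invariant after the fact. On a
full-genome simulated catalog the defaults produce ~383 regions out of a
385-bin ceiling with mean amplicon length ~256 bp (cap 280 bp).

## The synthetic cohort generator

The generator defines the study conditions the analysis is tested under.

**Segregation model.** Each embryo draws a pairing fidelity φ from a
mixture (`fidelity_mix`); each pair then segregates properly with
probability

$$p_\mathrm{eff} = \varphi + (1 - \varphi)\, p_\mathrm{random},
\qquad p_\mathrm{random} = 2p(1-p) = 0.5 \text{ at } p = 0.5,$$

where `p` is the per-chromatid chance of landing in the zygote. φ = 0 is
the pure random model (each chromatid an independent fair coin, per-pair
proper chance 50%); φ = 1 is fully faithful, meiosis-I-like segregation.
A nonsegregating pair stays in the zygote with probability
`retention_bias` (0.5 = no bias). Proper pairs orient at random.

The **inbred-like preset** (`inbred_like_mix()`) uses fractions
0.19/0.81 with effective proper probabilities 1.0/0.63, giving cohort
mean `20 × (0.19 + 0.81 × 0.63) = 14.0` proper pairs and a ~19%
complete-haploidization rate. The mixture is needed because a single
per-pair probability cannot reproduce both numbers under independence:
matching the 19% all-20-proper rate alone would need
`p = 0.19^(1/20) ≈ 0.92`, i.e. a mean of ~18.4, not 14. The
corresponding acceptance check is self-consistency of this construction,
not an independent validation.

**Observation model.** Per trio sample and panel variant, total depth is
negative binomial with mean 250 (the assay's design coverage; dispersion
`size = 8` gives realistic amplicon-to-amplicon spread, `Inf` the
deterministic limit), split binomially between the carried alleles.
Whole-genome-amplification dropout zeroes each carried allele's reads
independently with probability 0.1 per locus — no quantitative rate is
established for multiple-displacement amplification at these input
amounts, so 0.1 is a deliberately pessimistic placeholder whose effect is
sensitivity-tested (content accuracy stays ≥ 99% with ≥ 8 loci per
chromosome). Sequencing/amplification error flips each read to the
opposite allele with probability 0.002. Chromosomes absent from a sample
yield zero reads. The two blastomeres share the zygote genome and differ
only by independent noise.

**Meiotic (1n2c) control.** Intact MII oocytes of an F1 female carry
recombinant chromatids. Per chromosome we draw a Poisson number of
crossover breakpoints (uniform along the chromosome) and treat the two
chromatids as complementary strain mosaics sharing those breakpoints, one
segregating to the pronucleus and one to the PB2. This is a deliberate
simplification of four-chromatid meiosis — it preserves exactly the
features the analysis consumes (alternating homozygous blocks,
complementarity between the division products) without modeling chiasma
interference or chromatid choice.

What the generator does **not** emulate: amplification chimeras,
read-level artifacts, PB2 degradation kinetics (degradation appears only
as absent chromosomes), mosaicism within blastomeres, and copy-number
signal in depth. Passing tests therefore show correctness of the
inference chain under these statistical assumptions, not robustness to
every real-data failure mode.

## Genotype calling and chromosome-origin inference

Per-locus calls follow the depth-floor exclusions of single-cell amplicon
data: homozygous calls need ≥ 12 reads of the called allele, heterozygous
calls ≥ 24 total reads; anything shallower is `NO_CALL` ("not
amplified"). Two thresholds the floors do not determine were fixed as
conservative defaults: a heterozygous call additionally needs a minor
fraction ≥ 0.2, and a homozygous call tolerates at most 5% contrary
reads. Raising floors can only turn calls into `NO_CALL`s, never the
reverse (tested over the full 0..40 × 0..40 depth grid).

Chromosome content is a consensus over the chromosome's ordered
informative loci:

* `ABSENT` below `min_informative` (default 2) informative loci;
* `BOTH` with ≥ 2 heterozygous loci — a single HET is not accepted as
  evidence of two homologs, because dropout elsewhere routinely fakes
  homozygosity but a lone HET is equally easily faked by error;
* `SINGLE_A`/`SINGLE_B` when all retained homozygosity blocks agree;
  an isolated discordant locus (e.g. `A A B A A`) is absorbed as a
  dropout/error artifact;
* `RECOMBINANT_SINGLE` when ≥ 2 alternating strain blocks are each
  supported by ≥ 2 consecutive concordant loci — the block-support rule
  guards against dropout-faked switches at the cost of missing
  crossovers supported by a single terminal locus;
* `AMBIGUOUS` otherwise.

`detect_crossovers()` reports, per switch, the interval from the last
locus of one block to the first locus of the next.

**Detectability at panel resolution.** With ~9–28 loci per chromosome at
7-Mb spacing, a planted breakpoint is observable only if at least two
informative loci flank it on both sides, and two breakpoints falling
between the same adjacent loci cancel. At a planted rate of 1
crossover/chromosome the detected mean is therefore structurally below 1
(~0.7 noise-free genome-wide). The crossover acceptance check is split
accordingly: the planted truth rate must match the Poisson rate within
3 SE, and detected switches must equal an independent truth-projection
oracle exactly on every chromosome — together, rate recovery up to panel
resolution. Asserting the raw detected mean against the planted rate
would conflate assay resolution with detection errors.

## Trio QC and classification

A trio passes QC iff the blastomeres agree on every chromosome's content,
nothing is `AMBIGUOUS`, and chromatid accounting closes. For hybrids the
closure is literal — `copies(PB2) + copies(zygote) = 2` per pair with
`ABSENT → 0`, `SINGLE → 1`, `BOTH → 2` — which is a stricter and more
operational reading of "sequencing reads for all 40 chromosomes in all
three samples" (a literal nonzero-reads rule would exclude every
both-extruded pair, whose blastomeres legitimately carry nothing). For
inbred backgrounds copy number is not observable from genotypes (the
homologs are identical, and depth-based dosage is deliberately excluded
as unreliable in WGA material), so closure reduces to presence: each
chromosome must be detected on at least one side, and for fertilized
embryos in the zygote, which always carries the sperm homolog.

Classification is a per-background truth table (`PROPER`,
`BOTH_RETAINED`, `BOTH_EXTRUDED`, `UNDETERMINED`); the zygote state is
the blastomere consensus, and discordance fails QC rather than being
majority-voted — with two observations there is no majority. Per-embryo
summaries count proper pairs and zygote-retained chromatids (1 per proper
pair, 2 per retained pair); complete haploidization is all 20 pairs
proper, which forces exactly 20 retained chromatids.

## Null model and statistics

The Monte Carlo null flips two independent coins per pair
(`p_to_zygote = 0.5` each chromatid) and counts pairs landing on opposite
sides; exhaustive enumeration of the four pole assignments gives the
per-pair proper chance 2·0.5·0.5 = 50%, and the count per embryo is
exactly Binomial(20, 0.5) with mean 10. The simulation is checked against
this closed form by total-variation distance (< 0.01 at 10⁵ draws). The
null is parameterized per chromatid so retention-biased variants remain
expressible.

Cohorts are compared with the two-sided Wilcoxon rank sum test. The
implementation delegates to `stats::wilcox.test` behind a thin interface
that fixes the exactness policy: full enumeration when the combined
sample size is ≤ 12 and tie-free, otherwise the normal approximation with
tie-corrected variance and 0.5 continuity correction; the chosen path is
recorded in the result. The test suite verifies the exact path against an
independent `combn()` permutation oracle for *every* tie-free input with
total n ≤ 10. Two-sided p-values are used throughout since no sidedness
is pre-registered. Chromosome-length effects are assessed with the
Pearson correlation; note that with only 20 chromosomes a single cohort's
r has sampling sd ≈ 0.23 regardless of cohort size, so "no correlation"
is tested on the mean of r over replicate cohorts.

## Numerical and degenerate-input conventions

* Positions are 1-based inclusive everywhere internally; BED output is
  0-based half-open.
* An empty catalog designs an empty panel without error; empty cohorts
  are errors in summary statistics ("no QC-passing embryos") but fine in
  file round-trips.
* A cohort with no nonsegregating pair reports a `no_nonsegregation`
  sentinel rather than a 0/0 ratio.
* All generators take explicit seeds; cohort directories embed the seed
  in `meta.json`, and `run_pipeline()` derives each stage's seed from one
  run seed, making reruns checksum-identical.
* Depth emission treats `depth_dispersion = Inf` as constant depth — the
  deterministic limit used by the exact-recovery tests.

## Problem sizes

The packaged test suite and the workflow scripts use cohorts of 63/53/14
embryos (the study's arm sizes) for the narrative analyses, 10⁵ draws for
null-model checks, 2,000-embryo cohorts per setting for parameter
recovery, ~10⁴ profiled chromosomes for the dropout-accuracy bound, 500
oocytes for crossover recovery, and 100 random catalogs for panel-oracle
equivalence — sizes at which every stochastic bound sits at ≥ 3 standard
errors from its target.

## Known limitations

* Inbred verdicts rest on presence/absence only; a both-retained pair is
  indistinguishable from a proper pair if the PB2 chromosome also
  amplifies spuriously (not modeled), and true dosage methods would need
  depth calibration the assay does not promise.
* The crossover block rule cannot see breakpoints distal to the second
  locus from either chromosome end.
* The generator's dropout is locus-independent; spatially correlated
  amplification failure would hit the `min_informative` floor harder
  than the model predicts.
* Primer thermodynamics, multiplexing constraints and capture efficiency
  are out of scope: the designed panel is an in-silico target list, and
  empirical capture rates of a wet-lab panel are not reproducible here.
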