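---
title: "QTL-seq bulked-segregant mapping: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL-seq bulked-segregant mapping: model, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaqtl)
```

## The mapping problem

`bsaqtl` implements QTL-seq, the sequencing-era form of bulked-segregant
analysis, for biparental recombinant inbred line (RIL) populations. The
motivating system is seed lignan content in sesame: a low-lignan parent
(Goenbaek, 3.7 mg/g lignan, the sum of sesamin and sesamolin) crossed to a
high-lignan parent (Gomazou, 11.3 mg/g), advanced to F7 by single-seed
descent, phenotyped, and sequenced as two pools of 10 phenotypic extremes
("bulks") at roughly 21x depth alongside both parents.

At a variant site segregating between the parents, the **SNP/InDel-index**
of a bulk is the fraction of its reads carrying the allele that differs
from a chosen *consensus parent*; 0 means the bulk is fixed for the
consensus allele, 1 that it is fixed for the other parent's allele. At a
neutral locus both bulks sample the same 1:1 segregation and the expected
index is 0.5 in each. At a locus controlling the trait, the two bulks are
selected from opposite phenotypic tails and their indices diverge; the
**delta-index** (high-bulk index minus low-bulk index) approaches +1 or -1
with the sign determined by which parent donated the trait-increasing
allele. Window-averaged deltas outside a simulation-based null band are
called as candidate QTL regions.

Two features of the reference analysis shape the package design:

* **Dual consensus orientations.** The analysis is run twice, once with
  each parent as the consensus, and only regions recovered under both
  orientations are retained as *common* regions. In the original
  workflow the two orientations came from physically remapping reads to
  two consensus FASTAs, which introduces small asymmetries. `bsaqtl`
  emulates the two orientations by polarizing allele depths from a single
  VCF, so here they are *exact* mirrors (`polarize()` satisfies a strict
  count-swap involution, and window deltas satisfy
  `delta_B = -delta_A`). The asymmetry of the remapping approach is
  documented, not modelled: it cannot be reproduced without alignment.
* **Counter variants.** Inside called regions, variants whose index pair
  is exactly (1, 0) or (0, 1) — completely biased between the bulks —
  are mined as the most trustworthy markers and classified against gene
  models (upstream/UTR/CDS/intron/downstream, with CDS changes typed as
  synonymous, missense, nonsense, frameshift or in-frame).

## The synthetic cross

The simulator (`sim_config()`, `simulate_parental_variants()`,
`simulate_ril_population()`, `assign_phenotypes()`,
`simulate_bulk_reads()`) generates the full experiment the analysis
expects, plus a truth file of planted QTLs. Its defaults *are* the study
conditions: 257 F7 RILs, bulks of 10, Poisson(21) bulk depth, 13
chromosomes, and a variant catalog whose InDel share (0.1355) matches the
reported inventory (65,195 InDels of 481,298 variants). The catalog is
scaled down to 20,000 variants; at a 1 Mb window / 50 kb step that still
leaves ~75 sites per window, and marker density affects only the
granularity of window means, not the index model.

Choices where the study reports no value, made once and argued here:

* **Genome shape.** 13 chromosomes of 20 Mb (a ~260 Mb genome; sesame's
  assembled genome is ~350 Mb over 13 chromosomes — 20 Mb keeps desk-scale
  runtimes while preserving window counts per chromosome).
* **Recombination.** Haldane model (no interference), uniform 3 cM/Mb,
  giving a ~780 cM map over the 13 chromosomes, typical for sesame
  linkage maps. Crossovers are redrawn independently each selfing
  generation; F7 means 6 selfing generations after the F1, so the
  residual heterozygote frequency per locus is (1/2)^6 = 1.56%.
* **Truth model.** Three additive QTLs mirror the mapped loci: chr1 and
  chr11 increasing alleles from the *low* parent, a large chr6 allele
  from the *high* parent. The parental means pin down the arithmetic:
  `baseline + e1 + e11 = 3.7` and `baseline + e6 = 11.3`. With
  `(e1, e6, e11) = (1.2, 10.2, 1.4)` mg/g and baseline 1.1 mg/g the RIL
  population mean is 1.1 + (1.2+10.2+1.4)/2 = 7.5 mg/g, the observed
  population mean, and splitting the increasing alleles between the
  parents produces the observed transgressive segregation on both sides.
  Heterozygotes contribute a 0.5 allele dose (the additive model),
  both to the phenotype and to bulk allele frequencies.
* **Noise.** Gaussian with SD 0.5 mg/g (HPLC plus micro-environment
  scale for mg/g lignan measurements), truncated at zero. Sesamin is a
  jittered 72% fraction of lignan (the parental ratios are 73% and
  72.6%), sesamolin the remainder, so `lignan = sesamin + sesamolin`
  holds exactly for every record and r(sesamin, lignan) lands near the
  reported 0.98.
* **Sequencing.** Bulk depth Poisson(21), parents Poisson(50), symmetric
  per-read allele flip with probability 0.005. Which parent's allele is
  the VCF REF allele is randomized per site, so polarization is
  genuinely exercised rather than trivially aligned with REF.

What the generator does **not** emulate: reference/alignment bias (the
physical consensus-genome remapping), depth heterogeneity beyond Poisson,
LD with unsequenced causal sites, genotyping error in the parents, and
epistasis. Tests passing on this generator therefore validate the
*analysis arithmetic and calling logic* under the stated sampling model,
not robustness to alignment artifacts.

## The null band

The no-QTL band follows the established two-stage QTL-seq sampling
scheme, which the reference analysis invokes as the test "based on read
depth": for a bulk of *n* RILs, each member carries the B allele with
probability 1/2 (1:1 homozygote segregation; the 1.6% residual
heterozygosity is negligible at these depths and is ignored in the null),
the bulk allele frequency is the mean dosage, and read counts are
Binomial(depth, frequency) per bulk. `null_band()` simulates the delta
for every distinct depth pair (10,000 replicates by default) and takes
empirical type-7 quantiles at `(1 +/- level)/2` — the interpolation rule
is fixed for reproducibility. Windows are tested against the band at
their *median* site depths: deterministic, cheap, and conservative for
mixed-depth windows compared with per-site band aggregation.

Windows with fewer than 3 sites are reported but excluded from calling to
avoid single-site spikes. Because adjacent windows share 95% of their
span, window statistics are strongly autocorrelated; the band is a
per-window envelope, not a family-wise error control, and a null genome
shows slightly more than the nominal fraction of excursions (the test
suite bounds the pooled 95%-band exceedance at 10%).

## Region calling and naming

Windows outside the band at the calling level (default 99%) are merged
into regions when within one step (50 kb) of each other; each region
records its peak delta. Regions from the two orientations are *common*
when they overlap by at least 1 bp on the same chromosome — the matching
rule is not stated in the reference analysis, but this operationalization
reproduces its published 12/13/10 region accounting exactly, as the test
suite asserts from the shipped region table. A common region is **major**
when the larger of its two orientation peak |delta| values reaches 0.7;
the maximum (not both) is used because the published chr6 region clears
0.7 under only one orientation yet is named a major QTL — only the
max-rule yields exactly the three published names. The headline interval
reported for a major QTL is taken from the orientation with the larger
|delta|, again matching the published chr6 interval. Names follow
`q<Trait><chrom>-<k>` with `k` ordering regions along the chromosome.

## Counter variants and effect classes

`mine_counter_variants()` keeps sites inside common regions whose index
pair is (>= 1 - tol, <= tol) with both depths >= 8 (inheriting the site
filter); the default tolerance is 0 — the strict 1/-1 definition. The
classifier assigns exactly one class per variant-gene pair, a variant may
hit several genes (it is then reported once per gene), and CDS
substitutions are typed by mutating the reference codon and comparing
amino acids under the plain standard genetic code — initiator-codon
special cases are deliberately not modelled, and the exhaustive test
oracle translates with `no.init.codon = TRUE` accordingly. In-frame CDS
InDels get their own `cds_inframe` label, folded into the CDS column of
the per-region summary table. UTR classes require annotated UTR features;
without them, exonic non-CDS positions are labelled by their side
relative to the CDS. The published per-region counter counts are *not*
reproduction targets: they depend on the real reads and the Zhongzhi
No.13 v2.0 annotation.

## Allele effects and stacking

`single_locus_effect()` uses Welch's two-sample t test between the A and
B homozygote classes (the reference analysis shows significance stars
without naming its test; Welch is robust to the unequal class variances
that a segregating major QTL induces). Heterozygous and missing calls are
excluded (~1.6% at F7). `stacking_analysis()` groups lines by their
combination of favorable alleles — favorable taken from the truth file in
simulations, from the observed single-locus direction otherwise — and
applies one-way ANOVA with Tukey HSD compact-letter display
(`multcomp`); classes with fewer than 2 lines are dropped. With one
locus the ANOVA F reduces to the pooled t squared, which the tests
assert as an exact identity.

## Site filters and coordinates

Sites are retained when mapping quality >= 30, each bulk depth is in
[8, 250), and the parents are homozygous for different alleles;
multi-allelic and parent-missing sites are dropped with logged counts.
The depth filter is applied per bulk because the filter exists to bound
the variance of each bulk's index. Rejections are tallied by the first
failing rule in a fixed order so that tallies plus retained sites always
equal the input count, and filtering is idempotent. VCF and GFF3 I/O are
1-based inclusive; windows, regions and BED output are 0-based
half-open.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full design (257
RILs, 20,000 variants, 10,000 null replicates) in ~15 s per run, and the
20-seed recovery suites in a few minutes on one CPU; the smaller unit
fixtures (1,000-2,000 variants, 60-120 lines) were sized so each module
test completes in seconds. All stochastic stages consume explicit seeds;
the pipeline derives per-stage seeds from the global seed by fixed
offsets so any stage can be rerun in isolation, and a rerun with the same
configuration reproduces byte-identical tables.

## Known limitations

* The two orientations are exact mirrors here, so orientation
  intersection cannot drop regions on simulated data the way remapping
  asymmetries do on real data; the published region lists are shipped as
  a fixture to exercise that logic.
* The null band is an envelope per window, not a genome-wide error rate.
* The phenotype model is purely additive; dominance and epistasis are
  out of scope (the published allele-combination means are consistent
  with additivity).
* Start-codon and splice-site effects, and regulatory-motif annotation,
  are not classified.
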