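# bsaqtl

QTL-seq (whole-genome bulked-segregant) analysis for biparental RIL
populations, with the dual parental-consensus design used to map seed
**lignan content in sesame** (*Sesamum indicum*): a low-lignan x
high-lignan cross advanced to F7 by single-seed descent, phenotyped for
sesamin + sesamolin, and sequenced as two pools of 10 phenotypic extremes
at ~21x depth alongside the parents.

The package is for geneticists and breeders who want a tested, scriptable
version of that analysis — and a calibrated simulator to validate it
against a known truth.

## The statistic

At a biallelic site where the parents carry different homozygous alleles,
the **SNP/InDel-index** of a bulk is the fraction of its reads carrying
the allele that differs from a chosen *consensus parent*:

```
index = (reads with the other parent's allele) / (total informative reads)
```

so 0 means the bulk is fixed for the consensus allele and 1 fixed for the
other parent's allele. The scan statistic is

```
delta = index(high bulk) - index(low bulk)   in [-1, 1]
```

averaged in 1 Mb windows advancing by 50 kb, and compared against a
Monte-Carlo band for the no-QTL null (bulk composition ~ Binomial(n, 1/2)
over lines, reads ~ Binomial(depth, frequency) per bulk). The analysis is
run under **both** parental consensus orientations and only regions
recovered under both are kept; regions whose peak |delta| reaches 0.7 are
named major QTLs (`qLignan1-1`-style names). Inside called regions,
**counter variants** (index pair exactly 1/0) are mined and classified
against gene models, and marker genotypes at the QTLs are tested for
single-locus and stacked allele effects.

## Worked example

Simulate the full cross at the study design (257 F7 RILs, 20,000
variants, bulks of 10 at ~21x) and run the whole analysis:

```r
library(bsaqtl)
man <- run_pipeline(run_config(out_dir = "lignan_run", seed = 1))
str(man$counts)
#> List of 9
#>  $ variants_simulated: int 20000
#>  $ variants_read     : int 20000
#>  $ variants_filtered : int 19985
#>  $ sites_scanned     : int 19985
#>  $ regions_A         : int 3
#>  $ regions_B         : int 3
#>  $ common_regions    : int 3
#>  $ major_qtls        : int 3
#>  $ counter_variants  : int 173
man$major_qtls
#>          name chrom    start      end peak_delta_a peak_delta_b  peak_abs
#> 1  qLignan1-1 chr01 14550000 17850000   -0.8903892    0.8903892 0.8903892
#> 2  qLignan6-1 chr06 12850000 20000000    0.9940931   -0.9940931 0.9940931
#> 3 qLignan11-1 chr11        0  3450000   -0.9549876    0.9549876 0.9549876
```

Of 20,000 planted variants, 19,985 pass the site filters (mapping quality
>= 30, each bulk depth in [8, 250), parents homozygous and polymorphic).
The scan under each orientation calls 3 regions at the 99% level; they
intersect to 3 common regions, all clearing the 0.7 major-QTL bar — the
three planted loci, with the delta signs encoding which parent donated
the increasing allele (negative under orientation A for the chr1/chr11
alleles from the low parent, positive for the chr6 allele from the high
parent). `lignan_run/` holds every intermediate table: phenotypes, bulk
membership, the simulated four-sample VCF, per-site indices and window
scans per orientation, region/major-QTL tables, counter variants, marker
genotypes and allele-effect tests, plus a JSON manifest.

The published candidate-region table for the real cross ships as a
fixture and exercises the same calling logic:

```r
regs <- sesame_lignan_regions()
inter <- intersect_orientations(regs$goenbaek, regs$gomazou)
nrow(inter$common)
#> [1] 10
select_major_qtls(inter$common, major_qtl_config(0.7))$name
#> [1] "qLignan1-1"  "qLignan11-1" "qLignan6-1"
```

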