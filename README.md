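# ptmb — persistent tumor mutation burden

Tumor mutation burden (TMB) counts every nonsynonymous somatic mutation
equally, but mutations differ in how easily a tumor can shed them.
A mutation sitting on a segment with a single copy per cell (allele
state 1–0) can only be removed by homozygous deletion — usually lethal
for the region — and a mutation carried on several copies of a parental
haplotype cannot be removed by any single deletion event. These
**only-copy** and **multi-copy** mutations are *persistent*; everything
else is *loss-prone*. The **persistent TMB (pTMB)** — the count of
multi-copy plus only-copy mutations — is a refinement of TMB relevant to
immunotherapy response, where antigen loss by chromosomal deletion is a
resistance route.

`ptmb` is an R package plus a set of analysis drivers for computing pTMB
and its companion metrics from standard somatic-variant inputs:
allele-specific segmental copy number (FACETS-style), mutation calls
with distinct read counts (MAF-like TSV or VCF), and purity/ploidy
estimates.

## The model

For a mutation present at multiplicity *m* (mutant copies per cancer
cell) in a fraction *C* of cancer cells, with tumor purity α, local
tumor copy number *n*<sub>T</sub> and normal copy number
*n*<sub>N</sub> = 2, the expected variant allele fraction is

    V = m·C·α / (α·n_T + (1 − α)·n_N)

The mutant read count is binomial in the distinct depth, so an exact
(Clopper–Pearson) confidence interval on the VAF rescales into an
interval for the product *m·C*. Three rules resolve it:

1. the interval contains an integer ≥ 1 → the mutation is clonal with
   that multiplicity (nearest contained integer to the point estimate);
2. the interval lies below 1 → *m* = 1, *C* is the point estimate, and
   the mutation is subclonal unless *C* > 0.75;
3. the interval lies above 1 with no integer inside → *m* is the
   smallest integer rescaling the interval into [0, 1]; clonality as
   in rule 2.

Category assignment then follows the copy-number state: total copy
number 1 → only-copy; multiplicity > 1 → multi-copy; otherwise
loss-prone. Mutations on sex chromosomes or without allele-specific
copy number are excluded from every denominator.

Sample-level metrics include the fraction of the genome in allelic
imbalance, single-copy and multi-copy fractions, whole-genome doubling
(strictly more than 50% of autosomal length at major copy number ≥ 2),
and the background loss rates R<sub>D</sub> = (2·l<sub>D</sub><sup>HD</sup> +
l<sub>D</sub><sup>HM</sup>)/(2·l<sub>D</sub>) and R<sub>H</sub> =
l<sub>H</sub><sup>HD</sup>/l<sub>H</sub> over diploid- and haploid-state
chromosome arms (75% covered-length rules). Cohort tools cover TMB/pTMB
reclassification curves, Mann–Whitney comparisons, Cohen's *d*,
Spearman correlation with the *t* approximation, Fisher's exact test,
and longitudinal loss tracking in serial tumor pairs with both the
sample odds ratio and the conditional-MLE odds ratio. A synthetic-data
module generates FACETS-like profiles, binomially sampled read counts
and serial pairs with known ground truth.

## Worked example

```r
library(ptmb)

profile <- segment_profile("patient1", read_segments("segments.tsv"),
                           purity = 0.72)
muts <- read_mutations("mutations.tsv")
ann <- annotate_mutations(muts, profile)
ann[, c("chrom", "pos", "vaf", "total_cn", "multiplicity", "ccf",
        "clonal", "rule", "category")]
#>   chrom     pos       vaf total_cn multiplicity       ccf clonal rule   category
#> 1     1 5.0e+06 0.3500000        2            1 0.9722222   TRUE   R1 LOSS_PRONE
#> 2     1 1.5e+08 0.6421053        3            2 1.0000000   TRUE   R3 MULTI_COPY
#> 3     1 1.8e+08 0.1909091        3            1 0.7212121   TRUE   R1 LOSS_PRONE
#> 4     7 2.0e+06 0.3928571        1            1 0.6984127  FALSE   R2  ONLY_COPY

summarize_burden(ann, sample_id = "patient1")
#>   sample_id tmb ptmb clonal_ptmb multi_copy ... loss_prone n_excluded
#> 1  patient1   4    2           1          1 ...          2          0
```

Mutation 1 is a heterozygous-diploid clonal mutation (CCF ≈ 0.97) that a
single deletion could remove — loss-prone. Mutation 2's mC interval lies
above 1 with no integer inside, so it is multi-copy. Mutation 4 sits on
a single-copy segment: only-copy, hence persistent, even though its CCF
(0.70) is subclonal. The sample's pTMB is 2 of a TMB of 4.

The numbered scripts under `analysis/` are thin drivers over the same
functions: `01_simulate_cohort.R` builds a ground-truth cohort,
`02_multiplicity_recovery.R` sweeps recovery versus depth and purity,
`03_burden_reclassification.R` computes reclassification curves and
response associations, `04_genome_metrics.R` summarizes aneuploidy, WGD
and loss rates, and `05_longitudinal_loss.R` runs the serial-pair loss
analysis. Each writes its tables under `results/`.

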