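---
title: "Persistent tumor mutation burden: model, decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent tumor mutation burden: model, decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmb)
```

## The problem

A tumor under therapeutic pressure can lose mutations by subclonal
elimination or by chromosomal deletion. Deletion is only available for
some mutations: a mutation on a segment with total copy number 1 can
only disappear through homozygous loss of the region, and a mutation
present on more than one copy of a parental haplotype cannot be removed
by a single deletion event. Counting these *persistent* mutations —
only-copy plus multi-copy — gives the persistent tumor mutation burden
(pTMB), a refinement of TMB that is less confounded by the eliminable
(loss-prone) fraction of the mutation load.

This vignette documents the model this package implements, the
parameters that matter, the numerical and design decisions taken where
the procedure was genuinely open, what the synthetic-data generator does
and does not emulate, and known limitations.

## Multiplicity and cellular fraction

The inputs per mutation are the distinct mutant read count and distinct
depth; per sample, the purity $\alpha$ and the allele-specific segment
profile. With local tumor copy number $n_T$ and normal copy number
$n_N = 2$, a mutation at multiplicity $m$ and cellular fraction $C$ has
expected VAF

$$V = \frac{m\,C\,\alpha}{\alpha\,n_T + (1-\alpha)\,n_N}.$$

The mutant read count is modeled as Binomial(depth, $V$). An exact
Clopper–Pearson interval on $V$ (default level 0.95, `ci_level`)
rescales by the dosage factor $D = (\alpha n_T + (1-\alpha)n_N)/\alpha$
into an interval for $mC$, resolved by three rules:

* **R1** — interval contains an integer $k \ge 1$: clonal, $m = k$
  (see tie-break below), $C = \min(mC_{\text{point}}/m,\,1)$.
* **R2** — interval entirely below 1: $m = 1$, $C$ is the point
  estimate; clonal only if $C >$ `clonal_tolerance` (default 0.75).
* **R3** — interval entirely above 1 with no integer inside: $m$ is the
  smallest integer rescaling the interval into $[0,1]$, i.e. the
  ceiling of the upper bound; clonality as in R2.

The three cases are exhaustive and mutually exclusive: an interval
straddling 1 always contains the integer 1.

Numerical and policy choices here, made once and recorded:

* **CI flavor.** The exact (Clopper–Pearson) interval, chosen for its
  conservatism and because its endpoints can be verified independently
  by root-finding on binomial tail sums; the test suite does exactly
  that for every depth up to 30 at three confidence levels.
* **R1 with several contained integers.** The integer nearest the point
  estimate is assigned; half-way ties go to the smaller integer (the
  more conservative multiplicity). Integers considered start at 1 —
  an interval containing 0 but not 1 falls to R2.
* **Multiplicity cap.** A point mutation can occupy at most every copy
  of one parental haplotype, so the call is capped at the major allele
  copy number; the raw value is retained and flagged (`m_gt_major`).
  CCF above 1 after division (sampling noise) is capped and flagged
  (`ccf_capped`).
* **Degenerate inputs.** Zero mutant reads give no call
  (`zero_support`); total copy 0 under a mutation is flagged
  `cn_inconsistent` and excluded; mutations on sex chromosomes, in
  segment gaps, or on segments without allele-specific values are
  excluded categorically, never silently dropped.
* The clonality tolerance is applied to $C$ (for R2 with $m = 1$ the
  product $mC$ and $C$ coincide; for R3 we use the rescaled $C$, the
  same closure used for R2).

## Categories and burdens

Categories follow the copy-number state first: total copy number 1 is
only-copy regardless of the multiplicity call (a raw $m > 1$ there is
physically impossible and flagged `m_cn_conflict`); otherwise
multiplicity $> 1$ is multi-copy and the remainder loss-prone. TMB is
the raw count of assessed nonsynonymous mutations — not per-megabase —
and equals pTMB plus the loss-prone count by construction, an invariant
the tests enforce on every simulated sample. `persistent_mode =
"single_copy_only"` restricts pTMB to only-copy mutations, the
convention used for tumors dominated by copy-number loss
(mesothelioma); it is opt-in per sample, never auto-detected from the
tumor type.

Optional cohort filters reproduce published preprocessing: a minimum
VAF (0.10 where used) and indel exclusion. Panel restriction keeps
mutations inside BED intervals and recounts; copy-number annotation is
kept from the exome-wide profile on the assumption that allele-specific
copy number is derivable from targeted NGS itself.

## Genome metrics

Arm states use the covered length of segments clipped to the arm — not
the arm's nominal length — because real profiles rarely tile an arm
completely. An arm is diploid when at least 75% (`arm_state_fraction`,
ties count) of covered length is allele state 1–1; copy-neutral LOH
(2–0) does not qualify. Haploid arms need 75% at total copy 1. Loss
rates are then

$$R_D = \frac{2\,l_D^{HD} + l_D^{HM}}{2\,l_D}, \qquad
  R_H = \frac{l_H^{HD}}{l_H},$$

i.e. lost copies per copy at risk: a homozygous deletion in a diploid
arm counts twice in the numerator, and an absent arm class leaves the
rate undefined (`NA`) rather than zero. Aneuploidy fractions (allelic
imbalance, single-copy, multi-copy) use covered autosomal length with
assigned allele-specific values as the denominator — whether nominal or
covered length is the right denominator is not decidable from the
procedure's description, and covered length is the choice documented
here. Whole-genome doubling requires strictly more than 50%
(`wgd_fraction`) of autosomal length at major copy number $\ge 2$; the
strictness matters only at the exact boundary and is pinned by a test.
All metrics are invariant under segment splitting.

## Cohort statistics

High/low labels use the type-7 empirical quantile (linear interpolation
between order statistics) with a strict greater-than rule, so constant
vectors yield no high samples. The reclassification rate at a quantile
is the fraction of samples whose TMB and pTMB labels disagree; it is
symmetric in the two inputs and invariant under common strictly
monotone transforms. Group comparisons use the Mann–Whitney U test —
exact when both groups have at most 8 observations without ties,
otherwise the normal approximation with tie and continuity corrections;
the exact branch is verified against full permutation enumeration.
Cohen's $d$ uses the pooled SD with the fixed group order
nonresponders minus responders, so a responders-higher biomarker is
negative. Spearman correlation reports the asymptotic $t$
approximation for its two-sided p value. Fisher's exact test uses the
probability-mass two-sided rule. Discordant-classification analysis
labels at the second tertile and contrasts response rates across the
two discordant groups.

For the serial-pair odds ratio, two estimators are reported because
they legitimately differ: the sample odds ratio $ad/bc$ (Haldane 0.5
correction, flagged, when a cell is zero) and the conditional
maximum-likelihood odds ratio — the estimator attached to Fisher's
exact test — computed here by solving the conditional score equation
$E_\psi[X] = a$ on the noncentral hypergeometric support by bisection
to near machine precision, and verified against an independent
likelihood-maximization oracle to $10^{-6}$.

A mutation is lost at progression when its mutant allele fraction is
zero at an assessable locus; the default depth floor
(`min_progression_depth = 1`) is deliberately minimal — the loss rule
as published states no depth requirement — and stricter floors are
exposed for realistic use, with shallow loci flagged `unassessable` and
removed from denominators.

## The synthetic-data generator

The generator produces FACETS-like profiles and read counts with known
truth; its defaults are the study conditions for every test:

* purity uniform on 0.4–0.9 (the range typical of exome-based purity
  estimation in solid tumors); deep-recovery checks use 0.8–0.95;
* allele states drawn per segment from a diploid-dominant categorical
  distribution over {1–0, 1–1, 2–0, 2–1, 2–2, 3–1, 3–2, 4–2}, with
  30% of samples whole-genome doubled (all states doubled);
* 1–5 segments per arm at uniform breakpoints; one mutation per
  covered Mb unless stated; 80% of mutations clonal, subclonal CCF a
  Beta(2,2) rescaled below the clonality tolerance so truth clonality
  is unambiguous at generation time;
* a clonal mutation on a gained segment predates the gain with
  probability 0.5 (`p_early`), in which case its multiplicity equals
  the major copy number — multi-copy mutations arise from pre-gain
  timing, which is the biological reading of the multi-copy state;
* depth Poisson with mean 100 (250 in deep-recovery settings);
  overdispersion is available as an optional negative-binomial size
  but is off by default; mutant counts Binomial at the expected VAF;
* serial-pair loss probabilities per stratum: clonal loss-prone 0.21,
  clonal persistent 0.004, subclonal loss-prone 0.148, subclonal
  persistent 0.093 — the loss frequencies observed in serial NSCLC.

Truth categories are produced by the same `categorize()` rulebook the
estimator uses, a deliberate coupling tested explicitly: generator and
classifier cannot drift apart. All generators are pure functions of
(parameters, seed).

What the generator does *not* emulate: mutational signatures and
context, haplotype linkage between nearby mutations, segmentation
error and purity mis-estimation (copy number and purity are passed to
the estimator exactly as generated), subclonal copy number, and
read-level artifacts. Passing recovery tests therefore demonstrates
correctness of the estimation rules under the stated read-count model,
not robustness to upstream copy-number error.

Problem sizes used by the checked-in analyses and tests are chosen to
keep each run in seconds-to-minutes while leaving Monte-Carlo error
well inside the asserted margins: cohorts of 20–60 samples on 4–16-arm
templates, 400 replicates for null calibration of the group comparison,
200 replicates for odds-ratio recovery, and depth-250 cohorts of 50
samples for multiplicity/pTMB recovery.

```{r, eval = FALSE}
params <- sim_params(arms = read_arms("hg19"))
sim <- simulate_profile(params, seed = 1)
muts <- simulate_mutations(sim, params, seed = 2)
ann <- annotate_mutations(muts, sim$profile)
summarize_burden(ann, sample_id = "demo")
```

## Known limitations

* Purity and allele-specific copy number are trusted as given; errors
  there propagate directly into multiplicity (the dosage factor is
  linear in both).
* Only total copy number enters the expected-VAF denominator; allele
  phasing of the mutation (major vs minor haplotype) is not modeled
  beyond the major-copy cap.
* In whole-genome-doubled tumors only-copy regions are nearly absent;
  no special handling is applied, so single-copy-mode burdens in such
  genomes are legitimately near zero.
* The arm tables shipped for hg19/hg38 are cytoband-derived
  approximations and are inputs, not facts the package asserts: any
  table in the same format can replace them.
* MHC-binding predictions and expression medians for the
  neoantigen-burden counts are consumed as precomputed inputs; the
  package only applies the IC50 < 500 nM and nonzero-median-expression
  filters.
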