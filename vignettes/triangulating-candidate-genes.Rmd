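---
title: "Triangulating candidate genes in a two-line selective-breeding cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating candidate genes in a two-line selective-breeding cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two rat lines selectively bred for high (bHR) versus low (bLR) exploratory
locomotion diverge in a broad behavioral temperament — locomotion in a novel
environment, elevated-plus-maze (EPM) exploration and immobility, and
Pavlovian conditioned approach (sign- vs goal-tracking). After dozens of
generations of selection, the lines also differ in hippocampal gene
expression at thousands of genes. The analytic difficulty is that line
differences confound everything with everything: differential expression may
reflect causal variants, linkage with causal variants, or pure drift.

An F2 intercross breaks up this confounding. Crossing bHR with bLR founders
(F0), intercrossing the F1s, and phenotyping/genotyping/profiling the F2s
re-segregates alleles, so one can ask which line-divergent expression
*continues* to track behavior, which expression is driven by nearby genetic
variation (cis-eQTLs), whether that variation is actually segregated between
the founder lines, and whether the same variation colocalizes with behavioral
QTLs. `triangulatr` implements that whole chain of evidence as composable,
tibble-first stages, and ships a synthetic-cross generator so every stage is
testable against planted truth without any external data.

## Pipeline stages and their models

### Differential expression

Counts are filtered (a gene is dropped iff at least 75% of samples have
fewer than 1 read — the boundary is inclusive, which is our reading of the
"<1 read in 75% of subjects" rule), normalized by trimmed-mean-of-M-values
(TMM, via `edgeR`), transformed to log2 counts per million with prior count
0.5, weighted by the voom mean–variance trend (LOWESS span 0.5, the voom
default), fitted gene-wise by weighted least squares, and moderated by the
empirical-Bayes variance shrinkage of `limma`, with Benjamini–Hochberg FDR.
The founder model is

    y ~ line + sex + pct_rRNA + pct_intergenic

with bHR and male as reference levels, so a positive Log2FC means
upregulation in bLR. The F2 model replaces the line term with one continuous
behavior and adds dissector, PavCA exposure, and sequencing-batch dummies
(three batches by default in the simulator). Voom weights are on for
differential expression and off for the eQTL input, where a rank-based
inverse normal transform makes them moot.

### Concordance and the DEG set

Agreement between result sets is quantified by Pearson/Spearman correlation
of Log2FC and by a signed two-sided rank–rank hypergeometric overlap (RRHO)
map: both lists ranked from most-up to most-down, each grid cell scored by
the hypergeometric tail of the overlap count, signed by
enrichment/depletion. The two-line DEG set admits a gene with FDR < 0.10 in
either line-contrast result, or nominal p < 0.05 in both with consistent
sign. Behavior concordance then flags DEGs with at least one nominal
direction-consistent behavioral association, using a fixed sign convention
mapping each behavior onto the "bLR-like" axis (lower locomotion, lower EPM
distance, more immobility, fewer open-arm entries, lower PavCA index are
bLR-like). Set overlaps are tested by Fisher's exact test; we report the
sample (cross-product) odds ratio with the exact conditional p and
conditional-MLE confidence interval.

### Gene-set enrichment

The ranking statistic is the mean of sign-harmonized t-statistics across the
included analyses (line contrast plus the five behaviors); genes missing
from some analyses are averaged over the available ones by default (the
alternative — dropping them — is a config switch). Enrichment uses the
weighted Kolmogorov–Smirnov running sum (weight exponent 1) with a
gene-permutation null of size-matched random sets. We count null sets at
least as extreme in |ES| (two-sided), which makes null p-values uniform;
NES normalizes by the mean |null ES| of matching sign.

### cis-eQTL mapping

Expression is residualized on the technical covariates, transformed by the
rank-based inverse normal transform (Blom offset 3/8, average ranks for
ties), and augmented with the top five principal components of expression
and of the LD-pruned genotype matrix (greedy 50-SNP window, step 5,
r² > 0.5 — common-practice defaults, exposed in the configuration). Each
gene's window is ±1 Mb around the TSS (inclusive, strand ignored), SNPs at
MAF > 0.01. The per-gene top association is calibrated by permuting the
covariate-residualized phenotype (this preserves LD among SNPs, which the
approximation requires), recording the minimum nominal p per permutation,
and fitting a Beta distribution by maximum likelihood with
moments initialization; the empirical p is the Beta CDF at the observed
minimum. Gene-level FDR is Benjamini–Hochberg over top-SNP empirical
p-values (eGene: q < 0.05). Conditionally independent signals come from
forward stepwise conditioning, accepting a new signal only when its nominal
p beats the gene's significance threshold (the nominal p whose empirical p
equals the eGene level). Perfect-LD ties are broken by a seeded uniform
choice. The default 1,000 permutations per gene give stable Beta fits at
desk scale; the tests verify the approximation tracks direct rank-based
permutation p within ±0.02 on average.

### Allelic fold change and founder segregation

Effect sizes are expressed as allelic fold change (aFC): under the additive
cis-regulatory model the expected expression at alternate dose d is
μ(d) = c_r(2−d) + c_a d with aFC = log2(c_a/c_r). We fit by least squares
in log2 space on count + 1 with additive covariates, profiling the linear
terms and optimizing aFC on the box ±log2(100) (the conventional cap); the
pseudocount makes the estimator a stable, deterministic surrogate for a
count-scale likelihood fit, exact in the large-count limit. Founder-line
segregation of each eVariant is scored by Hedrick's standardized G'st with
Nei–Chesser small-sample corrections (harmonic-mean sample size and an
observed-heterozygosity term from the founder genotypes), and an eVariant is
called segregated when G'st strictly exceeds 0.27 — a threshold we treat as
a configuration constant, since it is not derivable from the estimator's
closed form. The aFC is then signed by the allele-frequency difference
(positive = predicted up in bLR), and predictions are compared to the
observed line contrast by correlation and sign concordance.

### SMR and the convergence gate

Behavioral summary statistics come from a per-SNP OLS scan with a sex
covariate (a deliberate stand-in for a mixed-model GWAS; an external summary
table with the same columns can be substituted). At each eGene's top
eVariant, colocalization with each behavior is tested by the
summary-data-based Mendelian randomization statistic
T = z²_eQTL z²_GWAS / (z²_eQTL + z²_GWAS), p from the upper χ²₁ tail, BH
within behavior. The directional statistic is sign(β_eQTL β_GWAS)·√T — the
z-scale choice; signed T itself is a config switch. A gene passes the
convergence gate iff it (1) is a DEG, (2) has a direction-consistent nominal
behavioral association, (3) is an eGene with a segregated eVariant, (4) has
a signed-aFC prediction matching its line-contrast sign, (5) colocalizes
with at least one behavior at SMR FDR < 0.10, and (6) does so with a
direction matching that behavior's differential expression. The expected
number of chance passes is estimated by jointly permuting the gene labels of
all differential-expression results while holding the genetic stages fixed.

## The synthetic cross

The generator is the package's test bed and defines its study conditions:

* **Genome.** Three chromosomes of 100 Mb / 100 cM, 2,000 SNPs and 100 genes
  each, uniform genetic map.
* **Founders.** Ten genotyped animals per line, Hardy–Weinberg within line.
  5% of SNPs are fixed for opposite alleles, 10% are partially segregated
  (frequencies 0 vs 0.55, placing their G'st near the segregation threshold
  so the threshold is genuinely exercised), and the rest share a Beta(0.8,
  0.8) background frequency.
* **Cross.** 50 F1s (one parent per line) and 250 F2s from random non-sib
  F1×F1 pairs — the F1 mating design is not something the study system pins
  down, so we chose the simplest design and note it here. Recombination is
  Haldane (Poisson crossovers, no interference), chosen for its closed-form
  map function, which the tests exploit. Phase is tracked so Mendelian
  consistency is checkable.
* **Planted architecture.** Ten pleiotropic candidate genes whose eVariant
  is a line-fixed SNP with |aFC| = 1 that also shifts all five behaviors by
  0.5 noise-SD per allele in the line-consistent direction; twenty eQTL
  genes with non-segregated background eVariants (|aFC| = 0.75); ten eQTL
  genes with partially segregated eVariants confined to chromosome 3, which
  carries no behavioral QTLs and thus acts as a negative control for
  colocalization. Behaviors share a latent factor (SD 0.7) loaded along the
  bLR axis, a sex effect of 0.3 SD on everything except locomotion, and unit
  noise.
* **Counts.** Negative-binomial with log-normal gene dispersions (median
  0.08), log-normal library sizes (CV ≈ 0.3), log-normal baselines, and
  modest gene-specific technical covariate effects (SD 0.15 log2) for sex,
  %rRNA, %intergenic, dissector, PavCA exposure, and batch.

What the generator does **not** emulate: read-level sequencing artifacts,
litter/maternal structure, relatedness beyond the two-generation pedigree,
selection over the breeding history, trans-regulation, and realistic LD
blocks within lines. Passing tests therefore demonstrate that the
statistical machinery recovers planted truth under a clean additive model —
not that real data meet these assumptions.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through stage-name hashing
  (`derive_seed`), so runs are bit-reproducible and stages independent.
* Degenerate Beta fits (identical permutation minima) fall back to the
  rank-based empirical p with a warning; a constant phenotype vector is an
  error for the inverse-normal transform; an all-zero count vector yields a
  flagged, NA aFC record; both-lines-monomorphic SNPs define G'st = 0;
  zero effect estimates give a zero-signed SMR direction and a flag.
* Problem sizes in the test suite and acceptance script (e.g. 5,000 null
  genes for FDR calibration, 200 null genes at 500 permutations for the
  eGene rate, 10 cohorts for gate recall) were chosen as the smallest scales
  at which the corresponding binomial error bars are informative.

## Known limitations

The OLS behavioral scan ignores residual relatedness among F2s (acceptable
in simulation, anticonservative in real pedigrees); the aFC estimator's
pseudocount slightly attenuates estimates for low-expressed genes; the
permutation count bounds attainable empirical p at 1/(n_perm + 1); and the
convergence gate treats its six criteria as a hard conjunction — a gene
missing one line of evidence is excluded outright rather than down-weighted.

## A worked run

```{r, eval = FALSE}
library(triangulatr)
cohort <- simulate_cohort(seed = 1)
tri <- triangulate(cohort, n_perm = 1000, seed = 1)
glance(tri)
tri$gate[tri$gate$pass, ]
autoplot(tri$f0_de)
plot_prediction_scatter(tri$segregation, tri$f0_de)
```
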