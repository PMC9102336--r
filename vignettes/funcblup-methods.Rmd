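---
title: "Methods: two-stage SNP-BLUP and gene-set association"
author: "funcblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage SNP-BLUP and gene-set association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcblup)
```

## The problem

Low-heritability traits in dairy cattle — calving ease, stillbirth,
temperament, milking speed — rarely show individual genes of large effect.
A productive strategy is to estimate *all* SNP effects jointly in one
mixed model and then to aggregate the evidence at the level of functional
gene sets (GO terms, KEGG pathways), asking whether a whole set of genes
carries more signal than expected.  `funcblup` implements this two-stage
analysis for progeny-based phenotypes (deregressed proofs, DRPs), together
with a synthetic-data generator that provides ground truth for testing.

## Stage 1: the SNP mixed model

All SNP effects are fitted simultaneously with a residual polygenic
effect:

$$ y = Xb + Z_1 g + Z_2 a + e $$

* $y$ — DRPs of the bulls; $X b$ — an overall mean.
* $Z_1$ — genotypes coded $-1/0/1$ (homozygous / heterozygous /
  alternative homozygous); $g \sim N(0, I\,\sigma^2_a/N_{SNP})$, i.e. the
  additive variance $\sigma^2_a$ is spread evenly over the chip.
* $Z_2$ — incidence of bulls into the pedigree;
  $a \sim N(0, A\,\sigma^2_{a^*})$ is the residual polygenic effect with
  the numerator relationship matrix $A$ and
  $\sigma^2_{a^*} = 0.4\,\sigma^2_a$, absorbing family resemblance the
  chip does not capture (incomplete linkage disequilibrium).
* $e \sim N(0, D\,\sigma^2_e)$ with $D = \mathrm{diag}(1/EDC_i)$: a DRP
  based on many effective daughter contributions is almost noise-free.

The solution is obtained from Henderson's mixed-model equations, built
exactly block by block ($R^{-1} = \mathrm{diag}(EDC_i)/\sigma^2_e$,
$G_1^{-1} = I\,N_{SNP}/\sigma^2_a$, $G_2^{-1} = A^{-1}/(0.4\sigma^2_a)$)
and factorized densely by Cholesky; the prediction-error variances (PEV)
of $g$ come from the inverse coefficient matrix.  `build_a_inverse()`
assembles $A^{-1}$ directly by Henderson's rules with inbreeding
(Mendelian-sampling variance $d_i = \tfrac12 - \tfrac14(F_s + F_d)$;
$\tfrac34 - \tfrac14 F$ for half-known parentage; unknown parents are
treated as unrelated non-inbred founders, no genetic groups).  Tests
verify both against the tabular $A$ and a dense GLS/BLUP oracle built from
$V = Z_1 G_1 Z_1' + Z_2 G_2 Z_2' + R$.

Variance components are *inputs*, as is usual for DRP evaluations
(`variance_spec()`, or `variances_from_h2()` to derive them from a
heritability and the realised DRP variance).  They are not estimated.

### Per-SNP tests

Each SNP is tested with the Wald statistic $W_j = \hat g_j /
\sqrt{PEV_j}$ against the standard normal, two-sided, with Bonferroni
correction over the panel.  The two reference lines of a Manhattan plot
are `bonferroni_threshold(0.05, 1)` = 1.96 and, at medium-density chip
scale (46,216 tests), `bonferroni_threshold(0.05, 46216)` = 4.88.

**Calibration of the PEV-based Wald ratio.**  The PEV is the standard
mixed-model choice for the uncertainty of a BLUP, but the ratio
$\hat g/\sqrt{PEV}$ is *not* a z-score under a complete null at desk
scale.  In eigendirections of the data information $b$, its null variance
is $\gamma b/(1+\gamma b)$ with $\gamma = \sigma^2_a/N_{SNP}$ — the
shrinkage factor itself.  Because the fitted polygenic effect absorbs
phenotypic signal down to an effective per-bull noise floor of about
$0.4\,\sigma^2_a$, the per-SNP information is capped near
$0.75\,n/N_{SNP}$ however precise the DRPs are, and the statistic is
strongly conservative whenever $N_{SNP}$ is not much smaller than $n$
(at $n/N_{SNP} = 2$ the genomic-control $\lambda$ under a simulated
complete null is about 0.4; at chip-like $N_{SNP} > n$ it falls below
0.1).  Only at industrial scale, where $\gamma b \approx 1$ on real
signal-bearing traits, does $\lambda$ sit near 1.  The package therefore
keeps the PEV convention — it is the convention consistent with inflation
factors reported close to 1 in large bull evaluations — and its test
suite asserts the *true* desk-scale properties: the test is conservative
(family-wise error well below its Bonferroni budget) and the dense-oracle
equivalence is exact.  Alternative conventions
($\sqrt{\sigma^2_g - PEV}$, and the per-SNP-null interpolation
$PEV(\sigma^2_g - PEV)/\sigma^2_g$) were evaluated and are likewise
mis-calibrated at desk scale; switching would buy nothing.

### Summaries

* `inflation_lambda()` — genomic control: $\mathrm{median}(W^2)$ divided
  by the $\chi^2_1$ median (0.4549).
* `variance_explained()` — the paper-style "significant SNPs explain X%"
  summary has no universal formula; the convention adopted here is the
  empirical variance of the genetic values built from the significant
  SNPs only (centred genotype columns), divided by the DRP variance, as a
  percentage.  This is a *convention*, documented rather than asserted as
  anyone else's.

## Annotation: SNPs to genes to terms

`map_snps_to_genes()` assigns a SNP every gene whose interval lies within
5,000 bp (distance 0 inside the gene, otherwise the distance to the
nearer edge; a SNP exactly 5,000 bp away is in, 5,001 bp is out; strand
ignored).  All genes within the window are assigned, not only the single
closest: one SNP can mark several functional elements.  The overlap
search runs on `GenomicRanges`; tests compare it to a brute-force
all-pairs scan including exact-boundary cases.

## Stage 2: the term-level mixed model

$$ y^* = u + Z^* p + e^*, \qquad p \sim N(0, P\,\sigma^2_p), \quad
   e^* \sim N(0, L\,\sigma^2_{e^*}) $$

* $y^*_j = |\hat g_j|$ — the absolute SNP effect from stage 1.
* $Z^*_{jt} = 1$ iff a gene assigned to SNP $j$ belongs to term $t$.
* $P$ — the term-overlap covariance: unit diagonal, off-diagonal the
  fraction of shared genes.  "Percentage of common genes" does not name
  its denominator; the package defaults to the Jaccard fraction
  (intersection over union) because it is symmetric — a requirement for a
  covariance matrix — and offers `min-size` and `geometric-mean` as
  alternatives.  Overlaps are computed on the gene universe reachable
  from the chip SNPs.  If the smallest eigenvalue falls below $10^{-8}$
  the spectrum is floored there and the matrix rescaled to unit diagonal
  (flagged on the returned object).
* $L$ — diagonal residual weights: 1 for SNPs assigned to at least one
  term, 10 for unassigned SNPs.  The value 10 is a convention of the
  modelled analysis with no stated derivation; it is exposed as
  `unassigned_weight` and defaults to 10.  Intergenic SNPs are retained
  (all-zero $Z^*$ rows), matching the stated $N_{SNP}$-dimensional $L$.
* $u$ — treated as a fixed overall mean.  With a fixed mean and a single
  all-ones term the term effect is confounded with $u$ and both the MME
  and the GLS oracle return $\hat p = 0$; `include_mean = FALSE` recovers
  the pure weighted-ridge reduction with closed form
  $\hat p = \sum y^*_j / (N + \sigma^2_{e^*}/\sigma^2_p)$.

Wald tests and Bonferroni correction are defined exactly as in stage 1,
with $m$ = the number of terms in the run; GO-like and KEGG-like
collections are modelled identically (both are gene sets) and analysed in
separate runs.  Although $y^*$ is non-negative, the two-sided convention
is kept for consistency with stage 1.

Since no procedure is stated for $\sigma^2_p, \sigma^2_{e^*}$, the
package estimates them by default with `estimate_term_variances()`:
restricted likelihood profiled over a log-spaced grid of ratios
$\sigma^2_{e^*}/\sigma^2_p$ (the scale has a closed-form REML estimate at
each ratio; the Woodbury identity keeps the cost linear in $N_{SNP}$).
Fixed values can be supplied instead.  The ratio is identified through
the spread of term effects, so its sampling error scales like
$\sqrt{2/N_{terms}}$ — with 20 terms, a factor-of-two scatter is
expected, which the recovery tests acknowledge.

Calibration of the stage-2 Wald test is checked in the weak-shrinkage
regime (diffuse term prior, $\sigma^2_p$ an order of magnitude above the
response variance): there the per-term type-I error sits within binomial
bounds of the nominal 5% and an injected mean shift of $0.5\tau$ on one
term's SNPs ranks that term first in over 90% of replicates.  Under
strong shrinkage the same statistic is conservative, for the reason
explained for stage 1.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every simulate operation is
deterministic given the seed (each operation derives its own RNG stream,
so call order does not matter).

* **Pedigree** — discrete generations; random pairing within the previous
  generation (no self-mating), a configurable number of offspring per
  pair.
* **Genotypes** — founder allele frequencies uniform on [0.01, 0.5],
  founders in Hardy–Weinberg proportions, and an independent gene-drop
  per SNP (one allele from each parent).  SNPs are deliberately
  *unlinked*: chip SNPs carry LD in reality, but no LD parameter is part
  of the modelled analysis, and unlinked drops exercise every estimator
  while keeping Mendelian checks exact.  Missing calls are inserted
  completely at random and coded `NA` — never a numeric sentinel.
* **Annotation** — non-overlapping genes (exponential lengths, mean
  40 kb) on 5 chromosomes of 10 Mb, so that with the 5 kb window roughly
  a quarter to a third of SNPs reach a gene — a realistic genic fraction
  for a medium-density chip; terms of 5–20 genes sampled with
  replacement across terms so they overlap.
* **Phenotypes** — $y = \mu + Z_1 g + a + e$ with $g$ i.i.d.
  $N(0, \sigma^2_a/N_{SNP})$ (optionally concentrated on a causal subset:
  `n_causal` SNPs carrying `causal_var_fraction` of $\sigma^2_a$), $a$
  generated through the pedigree recursion (founders
  $N(0, 0.4\sigma^2_a)$; offspring = parent average + Mendelian-sampling
  deviation with variance $\tfrac12\,0.4\sigma^2_a(1-(F_s+F_d)/2)$, using
  inbreeding from the tabular $A$), and $e_i \sim N(0, \sigma^2_e/EDC_i)$.
* **EDC** — uniform on [1000, 5000] by default, describing heavily
  progeny-tested AI bulls whose proofs are nearly noise-free; this
  matches the information regime of large bull evaluations.  EDCs are a
  design-level quantity keyed to the config seed, so replicate traits on
  one design share them and the factorized MME can be reused.
* **Default variances** — $\sigma^2_a = 0.1$, $\sigma^2_e = 0.9$
  (a low-heritability trait on a unit phenotypic scale, matching the
  0.03–0.12 range typical of calving and workability traits).

What the generator does **not** emulate: linkage disequilibrium and
recombination maps, selection, MACE deregression, X-chromosome
hemizygosity (all chromosomes are autosomal diploid; hemizygous coding is
not part of the modelled analysis), and per-trait EDC differences.
Passing tests therefore demonstrate correctness of the estimators under
the stated model — not robustness to LD structure or to deregression
artefacts in real proofs.

## Numerical choices

* Dense symmetric Cholesky of the full coefficient matrix (dimension
  $1 + N_{SNP} + n_{pedigree}$); a non-positive-definite system (e.g.
  duplicated SNP columns) is reported as such.  At the largest test size
  (6,001) one factorization takes well under a minute on one core.
* Mean imputation of missing calls between QC and the model (per-SNP mean
  of called genotypes); QC guarantees at least one call per SNP.
* QC order: a SNP failing both filters is counted under call rate.
* $P$ repair: eigenvalue floor $10^{-8}$, then rescaling to unit
  diagonal; symmetric by construction.
* REML grid default $10^{-2} \ldots 10^2$, 41 log-spaced points; a
  single-point grid is honoured as a fixed ratio.
* All tabular outputs are plain TSV; the run manifest (JSON) records
  seeds, thresholds and filter counts so every number is reproducible
  from the manifest and inputs alone.

## Problem sizes used by the test suite

The suite runs at desk scale, chosen so the full suite completes in a few
minutes: 50 random instances of up to 20 bulls / 30 SNPs / 25 pedigree
records for the oracle equivalences; 50 random pedigrees up to 50 animals
for the $A$-matrix identities; 1,000 bulls x 5,000 SNPs x 200 replicate
traits for the stage-1 null study; 1,000 bulls x 500 SNPs x 10 seeds for
the recovery study; 2,000 SNPs x 20 terms x 200/100 replicates for the
stage-2 calibration and power studies.

## Known limitations

* The PEV-based Wald ratio is conservative at desk scale (see above);
  significance counts on small synthetic designs understate what the
  same pipeline reports at industrial scale.
* The variance-explained summary and the overlap-denominator convention
  are documented choices among several defensible ones.
* Stage 2 treats $y^*$ as homoskedastic given $L$; in truth
  $\mathrm{var}(|\hat g_j|)$ varies with allele frequency.  The weight-10
  device is inherited as-is.
* No REML for stage 1; variance components are trusted inputs.
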