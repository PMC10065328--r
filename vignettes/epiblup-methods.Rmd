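---
title: "Epistasis-aware genomic prediction across years: models and methods"
author: "epiblup authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistasis-aware genomic prediction across years: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiblup)
```

## The prediction problem

Plant-breeding programmes phenotype doubled-haploid (DH) lines in field
trials and want to predict the performance of partially phenotyped material
in the next growing season.  `epiblup` treats the same biological trait
measured in two years as two traits of a bivariate mixed model, so that the
complete previous-year data can be borrowed when predicting the target
year.  Because DH lines are fully homozygous, every locus is coded with a
single bit: 0 and 1 are the two homozygous states, and a haplotype-block
variant (the presence of a shared chromosomal segment) is likewise a 0/1
predictor.

## Relationship kernels

Three covariance structures over lines are available; they differ only in
the design matrix behind the cross-product.

**GBLUP.**  The additive kernel follows VanRaden: with dosages
$x_{ij} \in \{0, 2\}$ (DH homozygotes), column allele frequencies $p_j$,
and $z_{ij} = x_{ij} - 2p_j$,
$$K = \frac{ZZ'}{\sum_j 2 p_j (1 - p_j)}.$$
For fully inbred DH panels the mean diagonal of $K$ is close to 2, which
is why `heritability()` multiplies the genetic variance by the mean kernel
diagonal before forming $h^2$.

**ERRBLUP.**  The full epistatic random-regression kernel uses one 0/1
column per unordered marker pair $(j, k)$ with $j \le k$, including
self-pairs, coding the presence of the $1/1$ combination (the elementwise
product of the two predictor columns).  A panel of $p$ predictors yields
$p(p+1)/2$ pairs, which is what makes the published panel sizes come out
at 4.4/5.5 million pairs for haplotype blocks, 323.5/456.4 million for
pruned SNP panels, and 125.6 billion for a full 501k array.  Columns are
centered by their combination frequencies $f$ and the cross-product is
scaled by $c = \sum f(1-f)$, in direct analogy to the VanRaden scaling.
That centering/scaling convention is this package's own fixed choice
(the natural random-regression analogue), and it is locked down by a
brute-force oracle in the test suite.

The kernel is never computed by materializing the interaction design.  For
0/1 panels, two lines sharing $s$ loci at value 1 share exactly
$s(s+1)/2$ pair combinations, so with $S = MM'$ the uncentered
cross-product is $(S^2 + S)/2$ elementwise, and all centering terms are
row/column means of that matrix.  The fast path is tested against the
materialized computation on hundreds of random instances.

**sERRBLUP.**  The selective kernel keeps only the top fraction $q$ of
pairs ranked by estimated effect variance.  Selection is computed once, on
the complete previous-year data of the target environment, never inside
cross-validation folds: a univariate REML fit with the full ERRBLUP kernel
yields genetic-value BLUPs $\hat g$, pair effects are backsolved through
the kernel/marker equivalence of random-regression BLUP,
$$\hat\alpha = \tfrac{1}{c} W' K^+ \hat g,$$
and each pair is scored by $\hat\alpha^2 f (1 - f)$.  Neither the
backsolve formula nor the variance score has a single canonical printed
form in the literature; the package fixes the forms above and validates
them by a planted-signal property (a pair carrying a dominant share of
genetic variance must surface in the top 1%) rather than by equivalence
with any specific implementation.  Ties are broken by lexicographic pair
order, which makes selections deterministic and nested across $q$.
The selected columns are materialized in batches (default $2^{20}$
columns); results are identical for any batch size.

Because the selection uses only previous-year phenotypes and the kernels
use only genotypes, withholding a line's target-year phenotype cannot
change any kernel or selection output; the test suite asserts this
directly.

## Mixed models

**Univariate.**  $y = 1\mu + g + e$ with $g \sim N(0, \sigma^2_g K)$ and
$e \sim N(0, \sigma^2_e I)$.  The restricted likelihood is profiled down
to the single ratio $\lambda = \sigma^2_g/\sigma^2_e$ through an
eigendecomposition of the observed kernel block and maximized by
one-dimensional search on $\log\lambda \in [-20, 20]$ — deterministic, no
iteration protocol needed.  When the kernel cannot separate $g$ from $e$
(e.g. proportional to the identity) the profile is flat; the fit is
returned with a warning.  BLUPs for unphenotyped lines come from the
kernel cross-block, $\hat g_{\text{all}} = \sigma^2_g K[\cdot,
\text{obs}] V^{-1}(y - 1\hat\mu)$.

**Bivariate.**  The two years share the kernel through
$u \sim N(0, G_0 \otimes K)$ with a free $2\times 2$ genetic
(co)variance matrix $G_0$; residuals are independent within and between
years.  The residual covariance is structurally zero because the two years
are distinct field seasons measured on different plots — a modelling
choice, not an estimate.  Fixed effects are per-year intercepts only: the
inputs are BLUEs, already adjusted for trial design.  Estimation is
EM-REML with average-information (AI) acceleration: the AI step is taken
only when it keeps the components admissible and does not decrease the
restricted likelihood, otherwise the monotone EM step is used, so the
log-likelihood trace is non-decreasing by construction.  After every step
$G_0$ is projected to the nearest positive semi-definite matrix
(eigenvalue clipping at $10^{-10}$ of the trace) and residual variances
are floored at $10^{-10}$ times the phenotypic variance.  Convergence
requires both a maximum relative component change below $10^{-6}$ and a
log-likelihood change below $10^{-6}$.  When the two years share no
phenotyped line and no initial values are supplied, the genetic covariance
is not identifiable and is fixed at zero with a warning.

**Two-stage protocol.**  Cross-validation fits follow a pre-fit protocol:
variance components are first estimated on the full two-year dataset with
an iteration cap of 100 and are used — converged or not — as initial
values for each fold's fit, which is capped at 50 iterations.  A fold fit
that does not converge falls back to the initial components as fixed
values, and BLUPs are computed at them (`fixedFallback`).  The full-data
pre-fit also supplies the genomic correlation
$r_g = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$ reported with each
evaluation.  The pre-fit intentionally sees all of both years (its role is
initialization and the $r_g$ estimate); per-fold training sets exclude the
fold's target-year test phenotypes.

## Evaluation pipeline

`runEvaluation()` executes a 5-fold cross-validation repeated 5 times
(configurable) over the target-year phenotyped lines.  Predictive ability
is the Pearson correlation between predicted genetic values and observed
test-set phenotypes, averaged over the fold-level values; prediction
accuracy divides by $\sqrt{h^2}$ with an externally supplied entry-mean
heritability.  Five model variants are supported: univariate GBLUP within
the target year, univariate GBLUP on the per-line average of both years'
phenotypes, and bivariate GBLUP / ERRBLUP / sERRBLUP.  Folds with fewer
than three phenotyped test lines or zero-variance predictions are skipped
with a message — a package rule for degenerate folds.  The mean over
converged-only folds is reported alongside the mean over all folds, and
the fraction of converged folds is part of every result.  OLS summaries of
the gain in predictive ability against genomic or phenotypic correlation
(`gainRegression()`) use the t-test p-value of the Pearson correlation,
without multiple-testing correction.

## LD pruning

`vifPrune()` mirrors the windowed variance-inflation-factor idea of
PLINK's `--indep` with the conventional parameter trio 50 / 5 / 2 as
defaults.  Windows of 50 predictors advance by 5; within a window the
predictor with the largest VIF is removed until all VIFs are at or below
the threshold, ties removing the later predictor in map order.  Sweeps
repeat until a full sweep removes nothing, which makes the operation
idempotent.  Exact equivalence with PLINK's internal order of operations
is a non-goal.  Zero-variance predictors are dropped at load (the target
panels are post-QC, so this is a guard) and are excluded from VIF
computation if they survive to this stage.

## The synthetic DH study

The simulator exists so every pipeline stage is testable without any
external dataset; its defaults describe the study conditions used
throughout the tests.

* **Panel** (`simulateDhPanel`): per region, founder haplotypes are random
  0/1 vectors with per-locus allele frequencies uniform on [0.1, 0.9]
  (avoiding monomorphic founders); each line copies one founder per locus
  and redraws the founder uniformly between adjacent loci with probability
  `switchRate`.  A low rate produces long shared segments — block LD —
  and `switchRate = 1` gives locus-wise independence.  The block panel
  has one indicator column per (region, founder): whether the line carries
  that founder over the majority of the region, ties toward the smallest
  founder index.  This majority-span rule is a deliberate simplification
  of windowed block-calling algorithms; the pipeline only needs a binary
  block-variant matrix.
* **Phenotypes** (`simulateTwoYearPhenotypes`): additive effects at
  `nAddQtl` SNPs plus interaction effects at `nEpiPairs` product columns,
  drawn jointly across years from a bivariate normal with correlation
  `rGTarget`.  Inducing the correlation at the effect level (rather than
  mixing genetic values post hoc) keeps each year's architecture and
  variance interpretable.  The epistatic component is rescaled per year so
  its share of genetic variance equals `epiVarFraction` exactly.
  Residuals are scaled per (year, environment) to the target
  heritabilities, and a configurable fraction of lines is left
  unphenotyped per year to emulate unbalanced multi-environment designs.
  Defaults — two years at $h^2 = 0.7/0.6$, $r_g = 0.9$, 250 lines — mirror
  a well-run maize DH programme with a strong across-year correlation.

What the generator does *not* emulate: real maize genetic maps, selection
and drift, genotype-by-environment interaction beyond independent
residuals, non-Gaussian trait distributions, and genotyping error.
Passing tests therefore demonstrate internal correctness and the
qualitative behaviour of the methods under the stated generative model,
not performance guarantees on any particular real dataset.

## Test and benchmark problem sizes

The packaged checks use sizes chosen to exercise each property clearly:
parameter-recovery runs use 300 lines × 500 SNPs with 25 replicates
(plus 15 null replicates); planted-pair selection uses 300 lines × 80
SNPs with one pair carrying ~60% of genetic variance (a "dominant" pair,
comfortably above the 50% threshold the property targets) over 50
replicates; the model-ordering benchmark uses 250 lines × 300 SNPs under
a purely additive architecture and 250 lines × 100 SNPs with ten
epistatic pairs carrying 60% of genetic variance; block-versus-SNP
equivalence uses `switchRate = 0`, the regime in which block variants tag
the causal founder segments exactly.  Fast-path/oracle equivalences run
on hundreds of random instances at $n \le 12$, $p \le 10$, where the
brute-force kernel is cheap.

## Known limitations

* Only two trait-year combinations are modelled; general multi-trait
  models are out of scope.
* The residual covariance between years is fixed at zero by design; data
  where the same plots are measured twice would violate this.
* The interaction coding targets fully homozygous panels.  Heterozygous
  material would need all four genotype-combination indicators per pair,
  which the 0/1 product coding does not represent.
* `vifPrune` is a convenience utility, not a PLINK replacement.
* Kernel construction is dense in the number of lines; panels of tens of
  thousands of lines would need bit-level or out-of-core engineering that
  this package deliberately avoids.
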