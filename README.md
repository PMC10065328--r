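# epiblup

Epistasis-aware genomic prediction across years for doubled-haploid (DH)
panels.

## The problem

Breeding programmes phenotype DH lines over successive growing seasons and
want to predict next season's performance of lines that are genotyped but
only partially phenotyped.  Two ideas improve on plain single-year genomic
prediction: (i) treat the same trait in two years as two correlated traits
of a **bivariate mixed model**, so the complete previous-year data are
borrowed; and (ii) model **pairwise epistasis**, but only through the
interactions that matter, selected on the previous year's data.  Because
the number of pairwise interactions grows as p(p+1)/2 — over 10⁸ for a
pruned SNP panel, over 10¹¹ for a dense array — the package also supports
haplotype-block variants as predictors, shrinking the interaction space by
orders of magnitude.

## Models

For lines with 0/1 genotypes (DH lines are fully homozygous) the package
builds three relationship kernels:

- **GBLUP** — the additive VanRaden kernel,
  `K = ZZ' / Σ 2pⱼ(1−pⱼ)` on 0/2 dosages;
- **ERRBLUP** — the full epistatic random-regression kernel over all
  p(p+1)/2 unordered marker combinations (self-pairs included), columns
  centered by their combination frequencies and scaled by `c = Σ f(1−f)`;
  computed by a closed-form fast path that never materializes the
  interaction design;
- **sERRBLUP** — the same kernel restricted to the top fraction *q* of
  pairs ranked by estimated effect variance `α̂² f(1−f)`, with effects
  backsolved from a previous-year ERRBLUP fit via `α̂ = (1/c) W′K⁺ĝ`.

Phenotypes of two years enter a bivariate REML mixed model
(`y = Xβ + u + e`, `u ~ N(0, G₀ ⊗ K)`, independent residuals per year)
fitted by EM-REML with guarded average-information acceleration, using the
two-stage protocol of pre-fitting components on the full data (≤ 100
iterations), initializing each cross-validation fold fit from them (≤ 50
iterations), and falling back to fixed initial components when a fold does
not converge.  Predictive ability is the Pearson correlation between
predicted and observed test phenotypes under 5×5-fold cross-validation;
accuracy divides by √h².  The genomic correlation between years,
`r_g = σ_g12/√(σ²_g1 σ²_g2)`, comes from the full-data fit.

A self-contained simulator generates DH panels with block LD (founder
mosaics with Markov switching), haplotype-block variants, and two-year
phenotypes with tunable heritabilities, genetic correlation and epistatic
variance share, so the entire pipeline is testable without external data.

## Worked example

Simulate a 250-line DH panel with ten epistatic pairs carrying 60% of the
genetic variance, then compare univariate GBLUP with the bivariate models:

```r
library(epiblup)

cfg <- simConfig(nLines = 250, pSnps = 100, nRegions = 8, nFoundersPerRegion = 4,
                 nAddQtl = 20, nEpiPairs = 10, epiVarFraction = 0.6,
                 h2Year1 = 0.8, h2Year2 = 0.8, rGTarget = 0.9, seed = 11001)
sim   <- simulateDhPanel(cfg)
pheno <- simulateTwoYearPhenotypes(sim$snp, cfg)
sim$snp
#> PredictorPanel: 250 lines x 100 snp predictors (mapped)

errblupKernel(sim$snp)
#> RelationshipKernel (errblup): 250 lines, 5,050 terms, scale c = 582.727, ridge = 1e-08

targets <- unique(pheno$records$line_id[pheno$records$year == 2018])
plan <- makeCvPlan(targets, folds = 5, reps = 1, seed = 21001)
spec <- function(model, q = NA_real_)
  modelSpec(model, q = q, predictorKind = "snp", environment = "E1",
            trait = "simtrait", targetYear = 2018, sourceYear = 2017)

runEvaluation(spec("uni_gblup_within"), sim$snp, pheno$records, plan, h2 = 0.8)
#> EvaluationResult [uni_gblup_within]: mean PA = 0.7229 over 5 folds (100% converged)
runEvaluation(spec("bi_gblup"), sim$snp, pheno$records, plan, h2 = 0.8)
#> EvaluationResult [bi_gblup]: mean PA = 0.7429 over 5 folds (100% converged)
runEvaluation(spec("bi_serrblup", q = 0.05), sim$snp, pheno$records, plan, h2 = 0.8)
#> EvaluationResult [bi_serrblup, q = 0.05]: mean PA = 0.7871 over 5 folds (100% converged)
```

Borrowing the previous year lifts the predictive ability of GBLUP
(0.723 → 0.743), and keeping the top 5% of interactions selected on the
previous year lifts it further (0.787) — the ordering the across-year
benchmark expects under a strongly epistatic architecture.  Each
`EvaluationResult` also carries fold-level predictive abilities, the
genomic and phenotypic correlation between years, and the fraction of
converged fold fits.

A thin command-line wrapper over the same functions lives at
`inst/scripts/epiblup.R` (`simulate`, `prune`, `kernel`, `cv`).

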