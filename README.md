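# iehc

Gene-level (SNP-set) association testing for **censored survival
outcomes**, integrating eQTL effect sizes as SNP weights under a
hierarchical Cox proportional-hazards model.

GWAS of survival phenotypes (e.g. cancer prognosis cohorts) are
underpowered SNP-by-SNP.  Grouping the SNPs of a gene and borrowing
external functional information helps: if a gene's effect on survival is
mediated through its expression, the known eQTL effect sizes
\(\beta_j\) of its SNPs are informative weights.  This package models the
per-SNP log-hazard effects hierarchically,

```
log λ(t)/λ0(t) = Gᵀα + Xᵀc,   α_j = β_j·θ + b_j,   b_j ~ N(0, τ),
```

so that "no association" is the joint null **H₀: θ = 0 and τ = 0**: no
effect through the eQTL-weighted burden score `Gᵀβ` (θ) and no residual
direct SNP effects (τ).  The package is aimed at statistical geneticists
analyzing cohort genotype + survival data (e.g. tumor cohorts) with
external eQTL summary statistics as weights.

## Tests provided

| test | examines | construction |
|---|---|---|
| burden | θ = 0 | 1-df Wald test of the score `s = Gβ` in a Cox fit on `[s, X]` |
| KM (variance component) | τ = 0 | kernel-machine score `Q = rᵀGGᵀr`, chi-square-mixture null (Davies-type characteristic-function inversion, Liu / Monte-Carlo fallbacks) |
| Fisher / adapt / optim | θ = 0 and τ = 0 jointly | combinations of the burden statistic with a **decorrelated** variance-component statistic, whose null fit includes the fitted burden term so the two components are asymptotically independent |
| ACAT omnibus | any of the above | Cauchy combination of the five p-values, valid under dependence |

The methods vignette (`vignettes/iehc-methods.Rmd`) derives each
construction, states all defaults and tolerances, and documents what the
simulator does and does not emulate.

## Worked example

```r
library(iehc)
set.seed(1)
cfg <- simConfig(theta = 0.3, tau = 0.02)   # signal through eQTL and direct effects
rep <- simulateReplicate(cfg)               # 165-subject expression cohort,
                                            # 300-subject survival cohort, S = 44 SNPs
res <- iehcTest(rep$G2, rep$weights, rep$pheno)
unlist(res[c("pBurden", "pKm", "pFisher", "pAdapt", "pOptim", "pAcat")])
#>     pBurden         pKm     pFisher      pAdapt      pOptim       pAcat
#> 0.254681206 0.001248919 0.002650542 0.002666704 0.002274055 0.002505293
```

Here most of the simulated signal flows through the direct effects
(τ = 0.02) and only weakly through the burden score, so the burden test
misses (p = 0.25) while the variance-component test and every joint test
detect the gene; the omnibus p (0.0025) tracks the best of the five
without knowing in advance which component carries the signal.

The detection-rate enrichment utility reproduces 2×2 comparisons of the
form "are nominally significant genes enriched among genes whose
survival effect sizes regress on their eQTL effect sizes":

```r
e <- enrichmentTest(259, 8274, 19, 2611)
sprintf("chi2 = %.2f, p = %.3g, rate ratio = %.2f", e$statistic, e$p.value, e$rateRatio)
#> "chi2 = 43.34, p = 4.61e-11, rate ratio = 4.20"
```

i.e. a 3.04% vs 0.72% detection rate — a fourfold enrichment — with the
continuity-corrected 1-df chi-square p-value.

## File-based workflow

`readGenotypes()` (TSV dosage or PLINK .bed/.bim/.fam), `readPhenotype()`,
`readWeights()`, `readGeneSets()` and `runStudy()` cover the study-level
path, with per-SNP QC (MAF, missingness, Hardy-Weinberg), allele
alignment against the weight table (strand-ambiguous SNPs dropped,
swapped orientations recoded), per-test Benjamini-Hochberg q-values, and
NA rows (with reasons) for genes that fail QC.  A thin command-line
front end with subcommands `test`, `simulate`, `calibrate`, `power` and
`concordance` is installed at `inst/cli/iehc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/iehc.R", package="iehc"))')" \
    test --genotypes geno.tsv --phenotype pheno.tsv \
         --weights weights.tsv --genesets genes.tsv --out results.tsv --seed 1
```

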