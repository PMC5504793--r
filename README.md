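# treegs

Genomic prediction and association mapping for open-pollinated forest-tree
breeding populations.

Tree breeders increasingly replace pedigree-based selection with
whole-genome prediction: genotype a progeny trial with a SNP chip, fit all
markers simultaneously, and select on genomic estimated breeding values
(GEBVs). `treegs` packages that entire analysis for the population type
where it is hardest to get right — small-Ne, family-structured,
open-pollinated (OP) trials measured in randomized complete block designs —
together with a forward simulator of such trials so that every estimator
can be validated against known truth.

## What it computes

For a trial with phenotypes `y`, block design `X` and SNP dosages `Z`
(coded 0/1/2 for the minor allele), the core model is the mixed model

    y = X b + a + e,    a ~ N(0, K σ²a),   e ~ N(0, I σ²e)

with `K` either the pedigree expectation **A** (1 on the diagonal, 0.25
between maternal half-sibs) or a genomic relationship matrix
**G = W W′ / 2Σp(1−p)** (VanRaden; the Powell unified-relatedness form is
used for LD corrections). REML profiling of `λ = σ²a/σ²e` on the spectrum
of `K` gives heritability `h² = σ²a/(σ²a+σ²e)` and BLUP breeding values;
the equivalent marker formulation `y = X b + Z m + e` is fitted either as
RR-BLUP (identical GEBVs, proven in the tests to 1e-6) or by Gibbs
sampling under the five classical marker priors — Bayesian ridge, Bayes A,
Bayes B, Bayes Cπ, Bayesian lasso. Predictive ability `r_gy` is the
correlation between validation phenotypes and GEBVs under 10-fold
cross-validation, under six SNP-subsetting designs, and under
relatedness-minimized train/validation splits (PCA + k-means, with a
random-split control).

Around the prediction core: call-rate/MAF filters and mean imputation,
PLINK-style windowed LD pruning, pairwise LD with kinship- and
structure-corrected variants (r², r²V, r²S, r²VS), Hill–Weir decay fitting
with threshold-crossing distances, LD-based effective population size with
parametric confidence intervals, and single-SNP association with
(`mlmaScan`) and without (`lmaScan`) a polygenic GRM term, with Bonferroni
and Benjamini–Hochberg control and Q-Q/Manhattan summaries. I/O covers
VCF, PLINK-1 binary, BED gene intervals, and plain TSV/JSON.

## Worked example

Simulate a trial the size of a published eucalypt study (Ne = 35, 24 OP
families × 31 progeny, 11 chromosomes), run QC, estimate heritability and
cross-validated predictive ability:

```r
library(treegs)

cfg <- simConfig(ne = 35, n_families = 24, progeny_per_family = 31,
                 n_markers = 20000, fst = 0.1, h2_true = 0.45,
                 cm_per_mbp = 20, seed = 42)
study <- simulateStudy(cfg)

geno <- filterSnps(study$geno)
#> filterSnps: 0 low call rate, 17396 below MAF threshold, 2604 retained of 20000
geno
#> GenotypeData: 744 samples x 2604 markers on 11 chromosome(s)
#>   missing rate 0.010 | median MAF 0.259

G <- grmVanRaden(imputeMean(geno))
#> KinshipMatrix (vanraden): 744 individuals | mean diag 1.017 | mean off-diag -0.0014

y <- study$phen$trait
X <- model.matrix(~ factor(study$phen$block))
fit <- remlFit(y, X, G)
round(c(h2 = fit$h2, sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e), 3)
#>       h2 sigma2_a sigma2_e
#>    0.439    0.453    0.579

cv <- crossValidate(y, X, K = G, method = "gblup", k_folds = 10, seed = 1)
round(c(r_gy = cv$mean_r, se = cv$se_r), 3)
#>  r_gy    se
#> 0.393 0.034
```

The simulated truth was `h2_true = 0.45`; REML on the genomic relationship
recovers 0.439, and a ten-fold cross-validation puts the predictive
ability at 0.39 ± 0.03 — in the range such trials report for growth
traits. The same objects feed the rest of the toolkit
(`pairwiseLD`, `fitLdDecay`, `estimateNe`, `lmaScan`/`mlmaScan`,
`sampleSubset`, `makeSplit`), and `runPipeline()` chains everything into
one seeded, reproducible report. One subtlety worth knowing:
`estimateNe()` on the family sample above estimates the effective number
of breeders behind those 24 families (about 24), not the base-pool Ne; a
random-mating sample drawn with `sampleRandomOffspring()` recovers the
pool value — the methods vignette discusses this distinction.

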