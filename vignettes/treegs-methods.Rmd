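---
title: "Models and methods behind treegs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind treegs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`treegs` implements the full analysis arc used in genomic selection studies
of open-pollinated (OP) forest-tree breeding trials: genotype quality
control, linkage-disequilibrium (LD) characterization with kinship and
structure corrections, LD-based effective population size, pedigree and
genomic relationship matrices, REML and Bayesian whole-genome regression
with cross-validated predictive ability, and mixed-linear-model
association. Because breeding-trial genotype/phenotype data are rarely
released, the package ships a forward simulator of such trials; every
statistical claim the test suite makes is checked against populations whose
ground truth is known by construction.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test bed does and
does not establish about real data.

## The synthetic breeding population

`simConfig()` / `simulateStudy()` generate a study with the anatomy of a
tropical eucalypt progeny trial:

* **Base pool.** A discrete-generation Wright–Fisher population of `ne`
  random-mating diploids per subpopulation drifts for `equil_gens`
  generations (default `4 * ne`, long enough for linked LD to reach its
  drift–recombination equilibrium). Candidate biallelic sites start at
  uniform-random frequencies; many drift to fixation, which is intended —
  the polymorphic yield after QC mimics a chip panel ascertained on a
  drifted population. Sites fixed in a pool are dropped from the active
  simulation and restored as constant columns afterwards; since fixation
  is absorbing without mutation, this is an exact shortcut, not an
  approximation.
* **Recombination.** Uniform map, `cm_per_mbp` centimorgan per megabase
  (default 1). Only the relative LD scale matters for the package's
  contrasts; analyses that need LD to decay visibly inside a window of a
  few megabases (decay fitting, GWAS calibration) raise `cm_per_mbp` in
  their study configurations rather than the chromosome count.
* **Structure.** With `fst > 0` one equilibrated ancestral pool is
  duplicated into two islands which drift independently for
  `round(2 * ne * fst)` generations — the diffusion-scale solution of
  `Fst ≈ t / (2 Ne)`. Two islands match the two-cluster structure
  typically reported for such trials; `hudsonFst()` verifies the realized
  divergence.
* **OP families.** Mothers are drawn without replacement; each offspring
  combines a maternal gamete with a pollen gamete from a random
  non-maternal adult of the same subpopulation (the random-mating pollen
  pool assumed by LD-based Ne estimation). Progeny of one mother are
  maternal half-sibs with expected additive relationship 0.25 — the test
  suite checks this both in the pedigree A matrix (exactly) and in the
  realized genomic relationships (stochastically).
* **Trait.** `n_qtl` causal loci are drawn uniformly among polymorphic
  markers with standard-normal allelic effects, rescaled so that the
  in-sample additive variance fraction equals `h2_true`; block effects
  `N(0, block_sd^2)` are laid out as a randomized complete block design
  with one tree per family per block while capacity lasts. With
  `h2_true = 0` the effects keep their drawn scale and the residual
  variance is inflated instead, so breeding values remain non-degenerate.
* **Missingness** is completely at random at `missing_rate` (defaults
  0.01, matching the aggregate missing rates such chips report).

Default sizes (24 families × 32 progeny, 11 chromosomes, Ne = 35) emulate
a published-scale trial of roughly 750 genotyped trees. What the simulator
deliberately omits: genotyping-chip error models, selection and mutation,
overlapping generations, field mortality/thinning, and multi-generation
pedigrees. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to
ascertainment or non-random missingness in real chips.

## Genotype QC and marker subsets

`filterSnps()` applies the two chip-QC axes with the boundary semantics
such studies print: call rate `>= cr_min` (boundary kept; default 0.90)
and either strict polymorphism (`MAF > 0`, when `maf_min = 0`) or an
inclusive frequency cut (`MAF >= maf_min`). `imputeMean()` replaces
missing calls by the marker's observed mean dosage — the same convention
the downstream regressions assume.

`ldPrune()` re-implements the windowed greedy pruning of the standard
`--indep-pairwise 100kb 1 0.2` recipe. Where the recipe leaves the removed
pair member unspecified, the package removes the lower-MAF member (ties:
the later position) — the variance-preserving convention — and computes
r² on mean-imputed dosages so the pass is deterministic. A post-hoc oracle
in the tests confirms no surviving within-window pair exceeds the
threshold.

`sampleSubset()` provides the six subset designs used to probe what drives
prediction: a nested chromosome-stratified size ladder (implemented via
fractional within-chromosome ranks, which makes nesting and proportional
allocation exact by construction), independent random draws, evenly spaced
SNPs (one per window, closest to the window midpoint — midpoint maximizes
spacing regularity where the choice is unspecified), genic/intergenic
partitions against a (synthetic) gene annotation, LD-pruned panels, and
single chromosomes.

## LD, decay, and effective population size

`pairwiseLD()` computes, for within-chromosome pairs up to `max_dist_bp`,
the classical r² (squared Pearson correlation of dosages) and corrected
variants in the Mangin style: structure correction (S) residualizes
dosages on the covariates; kinship correction (V) whitens them by the
inverse symmetric square root of a genomic relationship matrix (the Powell
construction is recommended, matching common practice); VS applies both.
Two numerical points matter:

* Frequency-centered GRMs are singular by construction (`K 1 = 0`), so
  the whitening adds a proportional ridge (1% of the mean diagonal) when
  the spectrum dips below `eig_floor`; without it the near-null directions
  dominate and corrected correlations saturate at 1.
* The whitened intercept and covariates are projected out *in the
  whitened space* (a GLS residualization). Ordinary centering is not
  enough: all whitened columns share a `K^{-1/2} 1` component that would
  otherwise masquerade as LD.

With identity kinship and constant covariates all four statistics coincide
to 1e-10, which the tests assert; on family-structured simulations the
corrected means sit below the raw means, reproducing the qualitative
reduction such corrections show on real trials.

`fitLdDecay()` fits the Hill–Weir drift-sampling expectation of r² as a
function of `C = c · d` at sample size `n` by nonlinear least squares
(three log-spaced starts, best residual sum of squares wins; all pairs
weighted equally). The distance at which the fitted curve crosses a level
(default 0.2) is solved numerically; if the curve stays above the level to
ten times the largest observed distance it is reported unbounded. Note a
degenerate corner: the expectation at zero distance is ≈ 0.45, so a
dataset with *no* LD at all drives the recombination scale upward and the
crossing distance toward zero — there is no interpretable LD extent, but
the fit itself does not diverge.

`estimateNe()` implements the LD-based (LDNe-style) estimator for random
mating: mean squared dosage correlation over physically unlinked pairs
(inter-chromosomal only, avoiding decay contamination — the method's
documented design choice here), minus the sampling expectation
`1/S + 3.19/S²` for samples of `S ≥ 30` individuals, transformed through
`Ne = (1/3 + sqrt(1/9 − 2.76 r²')) / (2 r²')`. Rare alleles are excluded
at `maf_cutoff = 0.05`. The parametric confidence interval treats the
number of independent comparisons as chi-square degrees of freedom on the
mean r². An adjusted r² at or below zero is reported as infinite Ne with a
one-sided interval; when the quadratic has no real root (severe drift LD,
Ne of a handful) the continuity limit `1/(6 r²')` is returned. Because the
sample must be a *random-mating* draw from the breeders, the generator
provides `sampleRandomOffspring()` next to the family sampler; applying
the estimator to a family-clustered sample estimates the (smaller)
effective number of breeders behind that sample.

## Relationship matrices, PCA, and relatedness splits

`pedigreeA()` builds the one-generation OP expectation (1 on the diagonal,
0.25 between maternal half-sibs, 0 otherwise); deeper pedigree recursion
is out of scope. `grmVanRaden()` is the standard
`W W' / (2 Σ p(1−p))` construction on frequency-centered dosages;
`grmPowell()` is the allele-frequency-standardized unified-relatedness
estimator used for the LD corrections. `genoPca()` eigen-decomposes the
VanRaden GRM (equivalently, the SVD of the centered scaled dosages — the
tests check the two routes agree to 1e-8).

`makeSplit()` reproduces the relatedness-controlled validation design:
individuals with any leading-PC score beyond `outlier_sd` standard
deviations (default 6 — the threshold is a package choice, configurable,
since published analyses report outlier counts but not rules) are set
aside, k-means with k = 2 on the leading two PCs defines the two sets, and
a random split of the same sizes serves as the control. Two PCs are used
because the emulated populations carry a single dominant structure axis;
the count is configurable.

## Mixed models and whole-genome regression

`remlFit()` maximizes the restricted likelihood of
`y = X b + a + e`, `a ~ N(0, K σ²a)`, by profiling `λ = σ²a/σ²e` on the
spectrum of `K`: one symmetric eigen-decomposition, then a 1-D search of
the restricted likelihood over `log λ ∈ [log 1e-6, log 1e6]` to 1e-8
tolerance. Boundary optima are flagged, not errors — pedigree-based
heritabilities of zero are a real outcome in such trials. Heritability is
`σ²a / (σ²a + σ²e)`; its standard error comes from the curvature of the
profile likelihood where the optimum is interior. Rank-deficient fixed
designs (a block absent from a training fold) are handled by dropping
dependent columns.

`rrblupEffects()` backsolves marker effects from the kinship-route fit;
when `G` is the VanRaden matrix of the same centered markers,
`W m̂` equals the GBLUP breeding values to numerical precision — the
central algebraic identity, asserted at 1e-6 relative in the tests.

`gibbsFit()` is a compiled single-site Gibbs sampler covering Bayesian
ridge regression, Bayes A, Bayes B, Bayes Cπ and the Bayesian lasso.
Common structure: fixed effects under a flat `N(0, 1e6 I)` prior, residual
variance scaled-inverse-χ²(ν_e, S_e). Marker priors: a common normal
variance (BRR); per-marker scaled-inverse-χ² variances (Bayes A); the same
with a point mass at zero and inclusion indicators (Bayes B); a common
variance with indicators and a Beta(1,1)-updated inclusion rate
(Bayes Cπ — Bayes B also updates its rate, starting from 1% inclusion);
and the double-exponential prior via exponential mixture scales with a
Gamma-updated regularization (BL). Hyper-scales default to
ν_e = ν_m = 5 with scales solved so the prior mode implies a 50% genomic
variance share — the conventions of the standard genome-wide regression
software — and everything is overridable. The sampler draws from R's RNG,
so `set.seed()` makes chains bit-reproducible. The production default
schedule is 200,000 iterations, 50,000 burn-in, thinning 5; the test suite
and the acceptance script use shortened chains (1,200–10,000 iterations)
on their reduced panels, which the conjugate-oracle check shows is ample
for posterior-mean accuracy at those sizes. With variances frozen, the
BRR posterior mean has a closed ridge-regression form; the sampler is
validated against it within Monte-Carlo error.

`crossValidate()` implements 10-fold (configurable) random partitions.
Validation predictions come from kinship projection
(`λ K_vt (λ K_tt + I)^{-1} r_t`) or marker effects (`W_v m̂`, centering
validation dosages at training allele frequencies). One decision the
source protocols leave open is whether validation phenotypes are
block-adjusted before correlating; the package removes training-estimated
fixed effects by default (`adjust_validation = TRUE`) on the grounds that
predictive ability should measure genetic merit, not shared block effects
— the toggle exposes the alternative.

## Association scans

`lmaScan()` is per-SNP least squares with covariates (vectorized through a
shared QR residualization); `mlmaScan()` estimates the polygenic variance
components once under the null by REML and then tests every SNP by
generalized least squares under the fitted covariance — the
population-parameters-previously-determined approximation, which is also
what the widely used implementations default to. The candidate SNP stays
in the GRM (plain MLMA, not leave-one-chromosome-out); on small, highly
structured panels this is known to leave the genomic inflation factor
slightly below 1, which is visible in the package's own calibration
checks. The structure covariate entering the scans is the leading PC score
(standing in for a two-cluster admixture assignment). Bonferroni and
Benjamini–Hochberg adjustments delegate to `p.adjust` and are asserted
against brute-force step-up arithmetic; `scanSummaries()` emits Q-Q and
Manhattan tables with `λ_gc = median(χ²)/0.4549`.

## Pipeline, seeds, and problem sizes

`runPipeline()` chains the stages in fixed order (simulate → filter →
LD/Ne → kinship → prediction/subsets/splits → GWAS → report) and writes
plain-text artifacts (VCF, TSV, JSON, BED). A single global seed spawns
per-stage child seeds through a fixed affine map, so any report number is
reproducible from config + seed; the test suite asserts bit-identical
reports across reruns. The default demo configuration simulates 300 trees
and 9,000 candidate sites with reduced MCMC chains and runs in well under
a minute on one core.

The test suite's study conditions are: heritability recovery at Ne = 35
with 24 × 31 progeny and 5,000 candidate sites over 20 seeds; the marker
plateau on a single 80,000-candidate (~10,000 polymorphic) panel;
relatedness splits over 10 structured populations; LD corrections over 10
seeds; decay ordering over 10 seed pairs at Ne 35 vs 50; Ne recovery over
20 seeds at S = 500 with ≥ 2,000 unlinked pairs; and GWAS calibration over
3 structured populations of 750 trees plus 10 single-QTL power replicates.
These sizes are the package's choices for a laptop-scale, fully
reproducible test bed; the same machinery scales to chip-sized panels.

## Known limitations

* The pedigree A matrix covers a single OP generation; bulked seed lots or
  pedigree errors (a documented reality in such trials) must be handled
  upstream.
* Ne estimation implements the random-mating, S ≥ 30 constants only, and
  inter-chromosomal pairs only; within-chromosome distance-thresholded
  pairs are not offered.
* Plain MLMA (no LOCO) slightly deflates test statistics on small
  structured panels, as discussed above.
* The Bayesian samplers run single-chain; convergence diagnostics beyond
  the built-in oracle checks are the user's responsibility for production
  chain lengths.
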