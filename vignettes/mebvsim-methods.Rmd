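---
title: "Simulating genomic prediction: population model, QTL architectures and estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic prediction: population model, QTL architectures and estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Marker-estimated breeding values (MEBV) predict the additive genetic merit
of individuals from genome-wide marker genotypes and effects estimated in a
phenotyped *training* population. How well this works depends on the
genetic architecture of the trait: how many loci (QTL) contribute, and how
the genetic variance is distributed over them. `mebvsim` provides a fully
simulated test bed for this question: a forward-in-time population
simulator that generates realistic linkage disequilibrium (LD) between
dense markers, a configurable QTL layer, three marker-effect estimation
methods, and an evaluation layer measuring prediction accuracy in a
non-phenotyped *evaluation* generation.

# The population model

The simulated genome has 4 chromosomes of 1 Morgan, each carrying 10,000
equally spaced loci. In the base population 4,000 loci (every tenth locus,
placed deterministically for reproducibility) are biallelic at frequency
0.50 and in linkage equilibrium; the rest are monomorphic. A population of
N = 100 diploids is then bred for 5,000 generations under drift,
recombination and mutation:

* every parent contributes exactly two gametes per generation, so the
  variance of contributions is zero and the effective population size is
  Ne = 2N − 1 = 199;
* per chromosome, meioses place a Poisson(1) number of crossovers at
  uniform positions (no interference); the starting strand is random per
  chromosome, so chromosomes assort independently;
* each transmitted gamete mutates at rate u = 1e-5 per locus; a mutation
  flips the allele;
* the 200 gametes are paired by uniform random union (`allow_selfing =
  TRUE`, the scheme under which the Crow–Kimura zero-contribution-variance
  formula gives exactly Ne = 2N − 1; a no-selfing variant is available).

Drift removes heterozygosity at rate 1/(2Ne) per generation while mutation
injects it; after roughly 4,000 generations the two balance at
mutation–drift equilibrium, H = 4Ne u /(1 + 4Ne u) ≈ 7.9e-3 (≈316
heterozygous loci per individual). The trajectory of observed
heterozygosity is recorded every generation so the approach to equilibrium
can be verified per replicate.

Two more generations complete a replicate, both without mutation (so no
new rare alleles appear after equilibrium): a training generation of 50
monogamous full-sib families of 10 (500 individuals, optionally 20 per
family for 1,000) and an evaluation generation of 250 families of 2 (500
individuals bred from the training generation).

The drift loop is implemented in C++ with bit-packed haplotypes (64 loci
per machine word): a recombinant gamete is `(A & ~M) | (B & M)` for a
strand mask M built from the crossover positions, and heterozygosity is a
popcount. All randomness flows through R's RNG, so a replicate is
bit-reproducible from its seed. A full 5,000-generation replicate takes a
few seconds.

# QTL architectures

QTL are assigned *after* the population is simulated, in the training
generation, which fixes the realized number of QTL exactly and lets the
same loci serve as QTL under different variance distributions. Eligible
loci have training-generation minor allele frequency above 0.10. Six
standard scenarios combine three QTL fractions — 5% ("low", ≈35 QTL), 25%
("intermediate", ≈172) and 50% ("high", ≈343) of the eligible loci — with
two variance modes: *equal* (every QTL has variance 1) and *unequal*
(every tenth QTL in genome order has variance 81, so 10% of the QTL carry
90% of the specified variance). The three QTL sets are nested (low ⊂
intermediate ⊂ high), and the equal/unequal pairs share QTL indices and
effect signs, so variance distribution is the only difference within a
pair.

Allele-substitution effects are derived from the specified per-QTL
variance Vq and the allele frequency p as |a| = sqrt(Vq / (2p(1−p))), the
standard identity making the realized Hardy–Weinberg contribution of each
QTL exactly Vq; signs are random. The source study's printed variance
tables suggest its own effect scaling was different (approximately
Vq/(2pq) realized per QTL), but its exact formula is not recoverable; we
keep the standard identity because every scale-free quantity (accuracy,
R², variance ratios) is unaffected, and absolute variance magnitudes are
out of scope. Markers are all polymorphic loci not selected as QTL in any
scenario, hence identical across scenarios within a replicate.

True breeding values are TBV = X_q a over the QTL dosages; the additive
variance σ²ₐ is the TBV variance in the training generation; phenotypes
add N(0, σ²ₑ) noise with σ²ₑ = σ²ₐ(1−h²)/h², default h² = 0.5 (so σ²ₑ =
σ²ₐ). Phenotypes exist only for the training generation.

# Population diagnostics

`expected_heterozygosity()`, `observed_heterozygosity()`, `adjacent_ld()`,
`sved_expected_ld()`, `founder_surviving_ld()` and `qtl_r2()` validate a
replicate against theory:

* adjacent-marker LD is the squared Pearson correlation of allele
  indicators across *haplotypes* (phase is known in simulation; a
  genotype-dosage option exists), averaged over within-chromosome
  adjacent pairs;
* Sved's expectation E[r²] = 1/(1 + 4Ne c) is the neutral-theory
  reference at marker spacing c;
* because new mutations insert markers between previously adjacent pairs,
  raw adjacent LD is not comparable to Sved's formula; the
  founder-surviving subset (base-generation biallelic loci still
  polymorphic at generation 5,000) is, and in our runs matches the
  source study to two decimals (≈0.035 at ≈174 surviving markers);
* `qtl_r2()` measures how well markers tag a QTL: markers are ranked by
  squared correlation with the QTL, the top 50 kept, greedily pruned so no
  retained pair exceeds |r| = 0.95 (keeping the marker in higher LD with
  the QTL; ties by locus index), and R² = c'K⁻¹c computed, falling back to
  dropping the weakest retained marker if K is numerically singular. This
  equals the OLS coefficient of determination of the QTL on the retained
  markers and bounds achievable prediction accuracy.

# Estimation methods

All three methods consume the training dosage matrix X (n × M) and
phenotypes y, and return per-marker additive effects; breeding values for
new individuals are MEBV = (X_new − training column means) · a, centered
deviations without an intercept (an intercept flag exists for raw-scale
predictions).

**Bayesian mixture (BM).** y = μ + Xa + e with per-marker indicators:
δ_j ~ Bernoulli(π), a_j | δ_j ~ N(0, v₁) or N(0, v₁/100), e ~ N(0, σ²ₑI).
Defaults: prior number of QTL 50 (π = 50/M), v₁ = 0.20 — interpreted on a
standardized-phenotype scale because raw phenotypic variances span orders
of magnitude across architectures; phenotypes are standardized internally
and effects rescaled on output, leaving accuracy unchanged. The Gibbs
sampler draws indicators from the two-component marginal with the effect
integrated out, effects and μ (flat prior) from normal full conditionals,
and σ²ₑ from its scaled inverse-χ² full conditional under a flat prior
(ν = −2); the chain runs 10,000 iterations with 1,000 burn-in (the
acceptance protocol allows 4,000/400 at desk scale) and reports posterior
means. Initialization: all effects 0, indicators 0, μ = mean(y), σ²ₑ =
var(y)/2; scan order is fixed marker order. A per-marker-variance variant
(`variance_model = "marker"`: scaled inverse-χ² prior of mean v₁,
ν₀ = 4.012, Metropolis–Hastings proposals from the prior) is provided; on
these simulations it performs indistinguishably from the fixed-variance
default, which we therefore keep as the literal reading of the method
description.

**LARS.** The least-angle regression path is computed on centered,
unit-norm predictors with Cholesky updates of the active Gram factor; an
exactly collinear entrant (duplicated marker columns do occur) is skipped
with a warning. Ten-fold cross-validation over the step index (same seeded
folds for every candidate step) picks the step minimizing mean squared
prediction error — the plain minimum, smallest step on ties — and the
full-data path is refit and cut at that step. The lasso modification
(coefficient sign-crossing drops) is available behind a flag but is not
the default, matching the plain algorithm.

**PLSR.** Univariate PLS (NIPALS-equivalent deflation). The component
search is iterative with a growing ceiling: cross-validate 1..10
components; if the optimum hits the ceiling, raise it by 10 and repeat,
capped at min(n, M). The collapsed coefficient vector B = W(PᵀW)⁻¹q at the
chosen count is returned. Components are orthogonal by construction; the
fit stops early if the deflated predictors or response are numerically
exhausted.

Cross-validation uses 10 folds for both LARS and PLSR (the fold count used
in the source study is unstated; 10 is the conventional default).

# Evaluation

`accuracy()` is the Pearson correlation between MEBV and TBV in the
evaluation generation; `msep()` the mean squared prediction error;
`unbiasedness_check()` compares var(MEBV) with accuracy² · σ²ₐ (ratio < 1
indicates shrinkage, > 1 inflation). `run_replicate()` orchestrates one
replicate — one simulation, one shared QTL/marker construction, one fit
per scenario × method — with seeds derived so that scenarios share the
simulated data exactly; `run_experiment()` and `summarize_results()`
aggregate means and standard errors (sample sd / √replicates) over
replicates, and `delta_vs_standard()` computes within-replicate deltas for
the one-at-a-time alternatives (h² = 0.25, MAF > 0.10 marker filter,
training size 1,000). For the 1,000-individual training alternative the
evaluation generation stays at 500: 500 of the 1,000 training individuals
are sampled as parents of 250 couples.

# What a green test establishes — and what it does not

The synthetic world reproduces the stated mechanics exactly, and its
robust diagnostics land on the reference values: equilibrium
heterozygosity ≈0.0079 (theory 0.0079, reference 0.0076), ≈1,440
polymorphic markers (reference 1,431 ± replicate noise), founder-surviving
adjacent LD 0.035 (reference 0.036). Statistics dominated by the fine
spatial and age structure of mutation-derived common markers come out
higher than the reference: adjacent LD among MAF > 0.10 markers ≈0.18
(reference 0.146) and, mildly, all-marker LD; mean QTL R² is
correspondingly ≈0.775 (reference 0.806). The estimators themselves were
cross-checked in development against the canonical `lars` and `pls`
implementations on identical data and agree to a few thousandths of a
correlation unit, so residual differences from the reference accuracies
reflect the simulated data, not the estimation code. Consequences worth
knowing: the drop of BM accuracy from the low- to the high-QTL scenario is
present but smaller here (≈0.08) than the reference reports (0.17), and
var(MEBV)/(r²σ²ₐ) for BM hovers just above 1 rather than below. Scenario-1 accuracy means over
5-10 replicates land around BM 0.70-0.74, LARS 0.72, PLSR 0.57-0.61
(reference: 0.77 / 0.75 / 0.66) with the reference's method ordering
preserved; the replicate-to-replicate standard deviation is about 0.07,
so 5-replicate means move by a few hundredths across seed sets.

# Numerical choices

* Crossover positions are uniform on (0,1) Morgan; the strand switches at
  the first locus with genetic position strictly greater than the
  crossover. Positions are index/10,000 Morgan within a chromosome.
* Mutation counts are Poisson(uL) per gamete with uniform positions;
  a position drawn twice flips twice (restores the allele).
* QTL-set sizes use round-half-to-even of fraction × eligible count.
* LARS uses 1e-10 as the collinearity/convergence epsilon; K-inversion in
  `qtl_r2()` falls back by dropping the weakest retained marker.
* Standard errors use the sample standard deviation (n − 1).
* Seeds: one root seed per replicate; sub-streams for QTL selection,
  effect signs, phenotypes and each estimator are derived with a fixed
  integer-mixing function, so any stage can be reproduced in isolation.

# Known limitations

* No interference, no sequence mutation model beyond allele flips, equal
  chromosome lengths only — by design.
* Absolute variance and MSEP magnitudes depend on the unrecoverable effect
  scaling of the source study and are out of scope; all comparisons are on
  scale-free quantities.
* The LD level among young common markers is sensitive to unstated details
  of the original simulator; see the acceptance notes above.
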