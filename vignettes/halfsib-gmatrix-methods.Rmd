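---
title: "Estimating and comparing G-matrices across environments: methods"
author: "halfsibG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing G-matrices across environments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfsibG)
```

# The scientific problem

When a population encounters a novel environment, its short-term adaptive
potential depends on how much additive genetic variance lies in the
direction of the phenotype that selection favors there. Two complications
make this a genuinely multivariate question. First, genetic variance is not
a single number: for a set of p traits it is the additive genetic
variance–covariance matrix **G**, whose leading eigenvector g_max is the
trait combination with the most genetic variance. Second,
genotype-by-environment interaction (G×E) means **G** itself can change
across environments, so the variance available to selection in a novel
environment need not resemble that in the native one.

`halfsibG` implements the full analysis chain for this question when the
data come from a paternal half-sib breeding design replicated across
environments (for example, full-sib seed families from sire × dam crosses
planted along an elevational gradient): estimate a posterior distribution of
**G** in every species × environment context, compare the resulting
G-matrices, and project ecologically meaningful directions — plasticity,
selection, and the phenotype of a locally adapted species — through each
**G**.

# The half-sib mixed model

Within one species × environment context, the trait vector of offspring *l*
from dam *j* nested in sire *i*, grown in block *k*, is modeled as

$$ y_{ijkl} = \mu + s_i + d_{j(i)} + b_k + e_{l(ijk)}, $$

with multivariate random effects $s_i \sim N(0, \Sigma_{sire})$,
$d_{j(i)} \sim N(0, \Sigma_{dam})$, $b_k \sim N(0, \Sigma_{block})$ and
residual $e \sim N(0, \Sigma_{resid})$. All p traits are analyzed jointly:
each component is a full p × p covariance matrix, never a set of
trait-by-trait variances. Under the half-sib design the between-sire
(co)variances estimate one quarter of the additive genetic (co)variances;
following common practice the package reports **G** on the sire-component
scale by default (`extractG(fit, scale = 1)`), with the ×4 additive scale one
flag away. Every *proportional* downstream quantity — eigenvalue
proportions, eigenvector angles, projection ratios — is identical under
either scale, which the test suite checks.

The full-factorial sire × dam crossing could also support a sire × dam
interaction term capturing dominance and epistasis; `halfsibG` deliberately
pools that term into the residual (the "paternal half-sib" analysis), which
costs nothing for the sire component, converges better, and estimates fewer
parameters. The dam term in the model is dam-within-sire, i.e. the full-sib
family effect.

## Sampler and priors

`fitHalfsib()` runs a Gibbs sampler with conditionally conjugate updates:
multivariate-normal full conditionals for $\mu$ and each set of random
effects, and inverse-Wishart full conditionals for the four covariance
components. The sampler is implemented in compiled code (RcppArmadillo), so
the permutation-based null distributions below — thousands of refits — run
at desk scale.

Priors default to inverse-Wishart with degrees of freedom $p + 1$ and scale
matrix $\bar v / n_c \, I$, where $\bar v$ is the mean phenotypic variance
across traits and $n_c$ the number of variance components (4 with a random
block term). This is the standard weakly informative heuristic for
variance-component models; both the degrees of freedom and all four scale
matrices are configurable through the `prior` argument. We considered a
parameter-expanded sampler (a working scale parameter per random term, which
helps mixing when variance components sit near zero) and decided against it:
for the balanced designs this package targets, plain conjugate updates mix
acceptably once thinned — `diagnoseChain()` applies the conventional bar of
lag-1 autocorrelation below 0.05 on the thinned draws — and the simpler
sampler is easier to verify against closed-form oracles. Chains of variance
components do decorrelate slowly, which is why the production-scale settings
use very heavy thinning (burn-in 150,000, thin 1,500, 2,000 saved draws);
the desk-scale default (`mcmcSettings()`: burn-in 5,000, thin 10, 1,000
draws) is meant for simulation studies and tests.

Because the sampler constrains covariance components to be positive
(semi-)definite, posterior distributions of genetic variances cannot overlap
zero, and "does the HPD exclude zero" is meaningless as a significance test.
`nullGTest()` instead randomizes offspring among sires *within blocks*
(preserving block differences and the multiset of family sizes), refits the
model per randomization, and flags an element of **G** when its observed
posterior mean exceeds the (1 − α) quantile of the null posterior means —
a one-sided exceedance test. Off-diagonal elements are tested on absolute
value since their null is centered at zero.

# Comparing G-matrices

`eigenG()` decomposes each **G** into eigenvalues (amounts of genetic
variance), variance proportions, and eigenvectors (directions), with a
deterministic sign convention: the largest-magnitude loading of each
eigenvector is made positive. `angleBetween()` computes
$\theta = \arccos(|r|) \cdot 180/\pi$, with r the vector correlation, so
angles lie in [0°, 90°] and are invariant to eigenvector sign flips;
`anglePosterior()` propagates posterior uncertainty by pairing draws from
two fitted posteriors by index (the chains are independent, so the pairing
is arbitrary and harmless).

## The genetic covariance tensor

To compare all m matrices in one framework, `covarianceTensor()` builds the
**S**-matrix: the covariance matrix (denominator m − 1) of the vectorized
unique elements of the m G-matrices. Vectorization stacks the p(p+1)/2
unique elements with off-diagonal elements weighted by √2, making the
Euclidean inner product of vectors equal the Frobenius inner product of
matrices; we state this convention explicitly because it is what makes the
eigenvectors of **S**, rearranged back into symmetric matrices (undoing the
weighting), an orthonormal set of *eigentensors* — independent axes of
variation among the G-matrices. Three exact identities pin the construction
down, and all are tested numerically:

* reconstruction: $S = \sum_k \lambda_k \, \mathrm{vec}(E_k)\,\mathrm{vec}(E_k)^T$;
* orthonormality: $\langle E_j, E_k \rangle_F = \delta_{jk}$;
* the coordinate-variance identity: the coordinates
  $\langle G_i, E_k \rangle_F$ of the m matrices on eigentensor k have
  variance exactly $\lambda_k$.

With m matrices the tensor has at most m − 1 nonzero eigenvalues (eight
contexts give seven). When posterior draw collections are supplied instead
of point matrices, **S** is computed per paired posterior draw and averaged;
eigentensors come from the posterior-mean **S**, and coordinates are
computed per draw, so each matrix's contribution to each axis is reported as
a posterior distribution. We chose per-draw coordinates (rather than
coordinates of posterior-mean matrices) because the coordinate posteriors
are the natural uncertainty statement for "which contexts drive this axis
of change".

Significance of eigentensors is assessed by `nullTensor()`, which simulates
changes in **G** due only to sampling: per null replicate and context, the
predicted (posterior-mean) sire effects are permuted among sires, phenotypes
are reconstructed as permuted sire effect plus the retained
dam/block/residual remainder, the model is refit, and the tensor of the null
G's recomputed. Null tensors are built by the same per-draw procedure as the
observed one, so observed and null eigenvalues carry comparable posterior
sampling noise. The exact reconstruction recipe is a design choice of this
package: permuting predicted sire effects among sires preserves every other
layer of the data while destroying exactly the sire-sampling structure the
test targets.

# Plasticity, selection, and projection through G

`plasticityVector()` is the difference in mean multivariate phenotype,
native environment minus novel (`groupMeans()` supplies the means,
measured individuals only); `nativeDirection()` is the analogous difference
between species at one environment. `computeD()` summarizes divergence of
all group means at once: the covariance matrix of group mean vectors
(denominator n_groups − 1), whose leading axes d_max and d_2 order the main
directions of mean-phenotype change. Among-group-mean covariance is the
standard construction for such a divergence matrix; its rank is at most
n_groups − 1.

`selectionGradient()` estimates viability selection from binary survival by
multiple logistic regression of survival on all traits jointly — the
multivariate fit is what supplies the $P^{-1}$ adjustment of
$\beta = P^{-1}s$. Coefficients are reported on three scales: logit;
probability (logit coefficients times the mean of fitted $\hat p(1-\hat p)$,
the average-gradient transform — the alternative of evaluating $p(1-p)$ at
mean survival is available via `derivativeAt = "meanFitness"`); and relative
fitness (probability scale divided by mean survival). The unit-length
relative-scale vector estimates the direction of selection. Selection is
only estimable where substantial mortality occurred *after* trait
measurement; the functions refuse contexts where fewer than 5% of measured
individuals died (configurable). Uncertainty comes from `bootstrapBeta()`,
a case-resampling bootstrap over individuals (family resampling would be an
alternative; case resampling matches the row-level logistic model being
resampled). `genotypicSelectionGradient()` repeats the analysis on family
means with quasi-binomial weighting by family size as a robustness check.

`projectThroughG()` computes the proportion of genetic variance in a
direction v:

$$ \frac{v^T G v}{\lambda_{g_{max}}} \in [0, 1]. $$

v is normalized to unit length internally. Without normalization the ratio
is not bounded by 1 and cannot be read as "a proportion of the maximum
genetic variation available", so the package always normalizes; the k-th
eigenvector yields exactly $\lambda_k / \lambda_{max}$, and **G** = I yields
1 for every direction. `projectPosterior()` propagates uncertainty over
bootstrap draws of v and posterior draws of **G**; by default each vector
draw is paired with one randomly chosen **G** draw (the full cross is
available but grows as n_boot × n_draws), and `hpdOverlap()` reports whether
two projection distributions overlap at a chosen HPD level.

# The synthetic-data generator

`simConfig()` + `simulateDataset()` generate data with exactly the structure
the model assumes, so every stage is testable without field data. The
generative defaults describe the emulated study conditions:

* 12 full-factorial 3 × 3 sire × dam crossing blocks (36 sires; a smaller
  final block is supported, e.g. 13 blocks with a 2 × 2 last block giving
  38 sires), parents never reused across blocks;
* 25 offspring per family per environment across four environments;
* five mean-standardized leaf traits (shape complexity, indent width and
  number, specific leaf area, flavonol content);
* sire variance 0.05, dam variance 0.05, block variance 0.02, residual 0.4
  per trait on the mean-standardized scale — evolvabilities of a few per
  cent of the squared mean, at the generous end of what leaf morphology
  shows;
* environment-specific trait means shifting by about ±12% across the
  gradient, alternating in sign across traits so plasticity is genuinely
  multivariate;
* trait-dependent logistic survival (default: directional selection on the
  first trait), family dropout of 0.13 (matching realized cross failure of
  roughly 94 families out of 108 attempted), and pre-measurement mortality
  of 0.3.

Sire effects are drawn *jointly* across environments: block-diagonal
per-environment sire covariances tied together by a cross-environment
correlation ρ_GE (default 0.5, a free knob — no empirical estimate of it
exists for these data), via the PSD construction
$L \,(R_\rho \otimes I_p)\, L^T$ with $L$ the block-diagonal matrix square
roots. This spans the interesting regimes: ρ_GE = 1 with equal
per-environment covariances gives no G×E; differing covariances and
moderate ρ_GE give G×E that can either boost or deplete variance along a
chosen direction. `scenarioConfig("B"/"C"/"D")` packages three canonical
two-environment versions: no G×E, G×E that increases variance along the
direction of selection at the novel environment, and G×E that decreases it.

Pre-measurement mortality is random with respect to phenotype by default —
the empirical justification being that families with high early mortality
do not differ systematically afterwards — but a trait-dependent option
(`mortalityBeta`) exists to study the bias that phenotype-selective early
mortality would cause. Dam effects are drawn once per dam and shared across
environments (the same dams contribute seeds everywhere); block effects are
independent per block × environment.

What the generator does *not* emulate: germination phenology, spatial
layout within planting blocks, non-Gaussian trait distributions,
measurement error distinct from residual variance, and selective mortality
before emergence. Passing tests therefore demonstrate correctness of the
estimation and comparison machinery under the assumed generative model, not
robustness to violations of it.

One structural caveat the simulations make visible: with the block term
identified with the *crossing* block, sires nest inside blocks (three per
block), and the random block effect absorbs part of the between-sire
variance — posterior sire variances at the default design run some 20%
below the generative value, with wide HPDs that still cover it. In field
layouts where planting blocks are crossed with families this absorption
largely disappears; `blockAsRandom = FALSE` (flat-prior block effects) is
available for such designs.

# Numerical choices and problem sizes

* Seeds: one master seed per stage; all sub-streams are derived
  deterministically from it, so identical seeds give bit-identical tables
  and reports (tested).
* Eigenvector and eigentensor sign convention: largest-magnitude element
  positive, applied before angles and coordinates are reported.
* Degenerate inputs: zero direction vectors are flagged and refuse
  normalization; `projectThroughG` refuses λ_max = 0; `eigenG` rejects
  asymmetric input beyond tolerance; HPD intervals use the
  shortest-interval construction.
* Tensor rank: with m contexts the S-matrix has rank ≤ m − 1 (covariance
  denominator m − 1); eigenvalues below 10⁻¹⁰ are reported as zero in rank
  counts.
* The replicated simulation studies in the test suite and acceptance script
  use reduced problem sizes chosen as the package's desk-scale defaults:
  G-matrix recovery at 12 blocks × 3 × 3 × 15 offspring with 20 replicates;
  null-test calibration at 4 blocks × 3 × 3 × 5 offspring, two traits, 50
  replicates of 100 randomizations; scenario ordering at 8 blocks with 20
  seeded runs. Production analyses should scale the MCMC settings up to the
  field-scale values noted above.

# Known limitations

* The sampler supports the two-level sire/dam nesting of the half-sib
  design, not arbitrary pedigrees (no animal-model relationship-matrix
  machinery) and no sire × dam interaction component.
* Null distributions require refitting the model hundreds of times;
  although each fit is fast, paper-scale nulls (1,000 randomizations ×
  8 contexts at production MCMC settings) are an overnight job, not a test.
* The logistic selection model estimates linear (directional) gradients
  only; no quadratic/correlational selection, no fecundity component, and
  no episode partitioning.
* Mean standardization defaults to per-species grand means across
  environments. Per-context standardization is supported but forces every
  standardized context mean to 1, which erases plasticity vectors; analyses
  mixing both conventions are not comparable.
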