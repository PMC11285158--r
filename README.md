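# halfsibG

Evolutionary quantitative genetics of multivariate phenotypes across
environments, for paternal half-sib breeding designs.

When seed families from sire × dam crosses are planted across an
environmental gradient, the additive genetic variance–covariance matrix
**G** of the measured traits can itself change with the environment
(genotype-by-environment interaction, G×E). Whether that change helps or
hinders adaptation depends on how much genetic variance lies in the
directions that matter: the direction of plasticity, the direction of
viability selection, and the direction of a locally adapted phenotype.
`halfsibG` implements the full analysis chain for this question:

* **Estimation.** The multivariate nested half-sib mixed model
  `y = μ + sire + dam(sire) + block + residual` is fit per
  species × environment context by a Gibbs sampler (conditionally conjugate
  inverse-Wishart updates, compiled with RcppArmadillo), yielding posterior
  draws of all four covariance components. Between-sire (co)variances
  estimate ¼ of the additive genetic (co)variances; **G** is reported on the
  sire-component scale (× 4 optional). Significance of **G**'s elements is
  tested against a null built by randomizing offspring among sires within
  blocks and refitting.
* **Comparison.** Eigenanalysis of each **G** (g_max, variance
  proportions), angles θ = arccos(|r|)·180/π between leading eigenvectors,
  and the genetic covariance tensor: eigenanalysis of the **S**-matrix of
  (co)variances of **G**'s elements across contexts, giving orthonormal
  eigentensors, per-context coordinates (posterior distributions), and a
  breeding-value-randomization null for eigentensor significance.
* **Selection and projection.** Viability selection gradients
  β = P⁻¹s from multiple logistic regression of survival on all traits,
  rescaled from the logit to the probability and relative-fitness scales,
  with case-resampling bootstrap; plasticity vectors Δx̄ = x̄_native − x̄_novel;
  species-difference (native-phenotype) vectors; and the projection
  (vᵀGv)/λ_gmax — the proportion of the maximum available genetic variance
  lying in direction v — propagated over bootstrap and posterior draws.
* **Synthetic data.** A generator with the full design structure
  (full-factorial sire × dam blocks, per-environment sire covariances tied
  by a cross-environment correlation, dam/block/residual layers, logistic
  survival, family dropout, pre-measurement mortality), so the entire
  pipeline is testable end to end without field data.

## Worked example

Simulate a two-environment design in which G×E *increases* genetic variance
along the direction of selection at the novel environment
(`scenarioConfig("C")`), then ask whether the data recover that:

```r
library(halfsibG)

cfg <- scenarioConfig("C", seed = 42L)          # 8 blocks of 3x3 crosses
tab <- meanStandardize(simulateDataset(cfg))
tab
#> PhenotypeTable: 1152 individuals, 3 traits
#>   traits: trait1, trait2, trait3
#>   species: sp_A | environments: native, novel
#>   measured: 1040 | survived (of measured): 528

fitNat <- fitHalfsib(tab, environment = "native",
                     mcmc = mcmcSettings(nBurnin = 2000, thin = 5,
                                         nSamples = 500, seed = 1))
fitNov <- fitHalfsib(tab, environment = "novel",
                     mcmc = mcmcSettings(nBurnin = 2000, thin = 5,
                                         nSamples = 500, seed = 2))
fitNov
#> GPosterior [sp_A @ novel]: 500 draws, 3 traits
#> posterior mean sire (co)variance matrix (G):
#>         trait1  trait2  trait3
#> trait1  0.2636 -0.0649  0.0139
#> trait2 -0.0649  0.3767 -0.0273
#> trait3  0.0139 -0.0273  0.1086

anglePosterior(fitNat, fitNov)$mean              # orientation change of gmax
#> [1] 48.4  (degrees, 95% HPD [11.3, 87.7])

sg <- selectionGradient(tab, environment = "novel")
sg
#> SelectionGradientResult [sp_A @ novel], n = 519, mean survival = 0.538
#>         logit   prob relative   unit
#> trait1 1.8017 0.3273   0.6088 0.9751
#> trait2 0.1125 0.0204   0.0380 0.0609
#> trait3 0.3937 0.0715   0.1330 0.2131

bb <- bootstrapBeta(tab, nBoot = 200, environment = "novel", seed = 3)
projectPosterior(bb, fitNov, label = "selection through G (novel)", seed = 4)
#> ProjectionResult [selection through G (novel)]: mean 0.5908,
#>   95% HPD [0.2648, 0.9720] (500 draws)
projectPosterior(bb, fitNat, label = "selection through G (native)", seed = 5)
#> ProjectionResult [selection through G (native)]: mean 0.1547,
#>   95% HPD [0.0342, 0.3210] (500 draws)
```

Reading the output: selection at the novel environment acts almost entirely
on trait 1 (unit direction 0.975 on trait 1), and the proportion of the
maximum available genetic variance lying in that direction is ~0.59 under
the novel-environment **G** but only ~0.15 under the native-environment
**G** — the pipeline recovers the variance-boosting G×E that the scenario
was built with. `runPipeline()` chains all of these stages (plus the
covariance tensor, D-matrix, and null tests) from a single YAML/list config
and writes a JSON report; `makeFixtures()` writes three small scenario CSVs.

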