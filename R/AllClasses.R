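#' @include halfsibG-package.R
NULL

## Central S4 classes. Validity methods enforce the structural invariants the
## downstream algebra relies on (PSD covariance blocks, nesting of dams in
## sires, unit-length eigenvectors, ...).

#' SimConfig: parameters of the synthetic breeding-design generator
#'
#' Describes a paternal half-sib crossing design (full-factorial sire x dam
#' blocks) whose offspring are planted in several environments, together with
#' the generative variance structure: environment-specific sire-level
#' covariance matrices (G x E), a shared dam covariance, block variance,
#' environment-specific residual covariances and trait means, logistic
#' survival coefficients, and nuisance processes (family dropout,
#' pre-measurement mortality).
#'
#' @slot nBlocks number of crossing blocks.
#' @slot siresPerBlock,damsPerBlock sires/dams per full-factorial block.
#' @slot lastBlockSires,lastBlockDams size of the final block when it is
#'   smaller than the rest (NA = same as the others).
#' @slot environments ordered character vector of environment labels.
#' @slot offspringPerFamilyPerEnv seeds planted per family per environment.
#' @slot traitNames names of the measured traits.
#' @slot mu list (one per environment) of trait mean vectors.
#' @slot SigmaSire list (one per environment) of sire-level covariance
#'   matrices; between-sire (co)variance equals one quarter of the additive
#'   genetic (co)variance.
#' @slot SigmaDam dam-within-sire covariance matrix (shared across
#'   environments: the same dams contribute seeds everywhere).
#' @slot sigma2Block scalar block variance (applied independently per trait
#'   and per block x environment combination).
#' @slot SigmaResid list (one per environment) of residual covariances.
#' @slot rhoGE cross-environment correlation of a sire's effects.
#' @slot betaSurvival list per environment with elements `intercept` (scalar)
#'   and `beta` (length-p logistic coefficients on centered traits).
#' @slot premeasurementMortality probability an individual dies before traits
#'   are measured.
#' @slot mortalityBeta optional length-p vector making pre-measurement
#'   mortality depend on the (latent) traits; zero vector = random mortality.
#' @slot familyDropout probability a cross produces no seeds.
#' @slot species species label stamped on generated rows.
#' @slot seed master RNG seed; all stage sub-streams derive from it.
#' @export
setClass("SimConfig", representation(
  nBlocks = "integer", siresPerBlock = "integer", damsPerBlock = "integer",
  lastBlockSires = "integer", lastBlockDams = "integer",
  environments = "character", offspringPerFamilyPerEnv = "integer",
  traitNames = "character", mu = "list", SigmaSire = "list",
  SigmaDam = "matrix", sigma2Block = "numeric", SigmaResid = "list",
  rhoGE = "numeric", betaSurvival = "list",
  premeasurementMortality = "numeric", mortalityBeta = "numeric",
  familyDropout = "numeric", species = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
  p <- length(object@traitNames)
  ne <- length(object@environments)
  msg <- character()
  if (ne < 1) msg <- c(msg, "environments must be non-empty")
  if (object@nBlocks < 1 || object@siresPerBlock < 1 ||
      object@damsPerBlock < 1 || object@offspringPerFamilyPerEnv < 1)
    msg <- c(msg, "design counts must be positive")
  for (nm in c("mu", "SigmaSire", "SigmaResid")) {
    if (length(slot(object, nm)) != ne)
      msg <- c(msg, sprintf("%s must have one element per environment", nm))
  }
  for (S in object@SigmaSire) if (!isPSD(S) || nrow(S) != p)
    msg <- c(msg, "each SigmaSire must be symmetric PSD of trait dimension")
  for (S in object@SigmaResid) if (!isPSD(S) || nrow(S) != p)
    msg <- c(msg, "each SigmaResid must be symmetric PSD of trait dimension")
  if (!isPSD(object@SigmaDam) || nrow(object@SigmaDam) != p)
    msg <- c(msg, "SigmaDam must be symmetric PSD of trait dimension")
  if (any(vapply(object@mu, length, 1L) != p))
    msg <- c(msg, "each mu must have one mean per trait")
  if (object@sigma2Block < 0) msg <- c(msg, "sigma2Block must be >= 0")
  for (pr in c(object@premeasurementMortality, object@familyDropout))
    if (pr < 0 || pr > 1) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(object@betaSurvival) != ne)
    msg <- c(msg, "betaSurvival must have one element per environment")
  if (abs(object@rhoGE) > 1) msg <- c(msg, "rhoGE must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' PhenotypeTable: individual-level breeding-design records
#'
#' One row per planted individual: pedigree (sire, dam), crossing block,
#' species and environment labels, the measured trait vector, and the
#' emergence / measurement / survival flags. Trait cells are present iff
#' `measured == 1`; `survived` is defined only for emerged individuals.
#'
#' @slot data data.frame with columns `individual_id`, `sire_id`, `dam_id`,
#'   `block_id`, `species`, `environment`, one column per trait, `emerged`,
#'   `measured`, `survived`.
#' @slot traitNames character vector naming the trait columns.
#' @export
setClass("PhenotypeTable",
         representation(data = "data.frame", traitNames = "character"))

requiredPhenoCols <- c("individual_id", "sire_id", "dam_id", "block_id",
                       "species", "environment", "emerged", "measured",
                       "survived")

setValidity("PhenotypeTable", function(object) {
  d <- object@data
  msg <- character()
  miss <- setdiff(c(requiredPhenoCols, object@traitNames), names(d))
  if (length(miss))
    return(sprintf("missing required column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(d$individual_id))
    msg <- c(msg, "duplicate individual_ids")
  # parents are unique to one crossing block: each dam (and sire) is mated
  # only within its block's full-factorial sire set
  for (parent in c("dam_id", "sire_id")) {
    key <- unique(d[, c("block_id", parent)])
    if (anyDuplicated(key[[parent]]))
      msg <- c(msg, sprintf("a %s appears in two crossing blocks",
                            sub("_id", "", parent)))
  }
  tr <- as.matrix(d[, object@traitNames, drop = FALSE])
  if (nrow(d)) {
    measured <- d$measured == 1
    if (any(!stats::complete.cases(tr[measured, , drop = FALSE])))
      msg <- c(msg, "measured individuals must have complete trait values")
    if (any(measured == 0 & stats::complete.cases(tr)) &&
        any(!measured & apply(!is.na(tr), 1, any)[!measured]))
      msg <- c(msg, "unmeasured individuals must have missing trait values")
  }
  if (length(msg)) msg else TRUE
})

#' StandardizationReference: per-trait reference means for mean
#' standardization
#'
#' @slot means named list: one numeric vector of per-trait reference means
#'   per species.
#' @slot source one of "species" (per-species grand mean), "context"
#'   (per species x environment mean), "user".
#' @export
setClass("StandardizationReference",
         representation(means = "list", source = "character"))

setValidity("StandardizationReference", function(object) {
  if (any(vapply(object@means, function(m) any(!is.finite(m) | m == 0), TRUE)))
    return("reference means must be finite and nonzero")
  TRUE
})

#' MCMCSettings: chain length parameters for the Gibbs sampler
#'
#' @slot nBurnin burn-in iterations discarded.
#' @slot thin thinning interval between saved draws.
#' @slot nSamples number of saved posterior draws.
#' @slot seed RNG seed for the chain.
#' @export
setClass("MCMCSettings", representation(
  nBurnin = "integer", thin = "integer", nSamples = "integer",
  seed = "integer"))

setValidity("MCMCSettings", function(object) {
  if (object@nBurnin < 0 || object@thin < 1 || object@nSamples < 1)
    return("nBurnin must be >= 0; thin and nSamples positive")
  TRUE
})

#' GPosterior: posterior draws of the half-sib variance components
#'
#' Holds the saved Gibbs draws of the four covariance components of the
#' nested half-sib model for one species x environment context. G is defined
#' from the sire component via a scale factor (`extractG`): the between-sire
#' (co)variances represent one quarter of the additive genetic (co)variance.
#'
#' @slot species,environment context labels.
#' @slot traitNames trait names (dimension p).
#' @slot sigmaSire,sigmaDam,sigmaBlock,sigmaResid p x p x nSamples arrays of
#'   posterior draws.
#' @slot mu nSamples x p matrix of posterior draws of the trait means.
#' @slot effects list of posterior-mean random effects (`sire`, `dam`,
#'   `block` matrices, `mu` vector) used for breeding-value randomization.
#' @slot modelData list with the model frame (`Y`, integer `sire`, `dam`,
#'   `block` indices and their labels) so the model can be refit on
#'   reconstructed data.
#' @slot mcmc the MCMCSettings used.
#' @export
setClass("GPosterior", representation(
  species = "character", environment = "character", traitNames = "character",
  sigmaSire = "array", sigmaDam = "array", sigmaBlock = "array",
  sigmaResid = "array", mu = "matrix", effects = "list",
  modelData = "list", mcmc = "MCMCSettings"))

setValidity("GPosterior", function(object) {
  p <- length(object@traitNames)
  for (nm in c("sigmaSire", "sigmaDam", "sigmaBlock", "sigmaResid")) {
    a <- slot(object, nm)
    if (length(dim(a)) != 3 || dim(a)[1] != p || dim(a)[2] != p)
      return(sprintf("%s must be a p x p x nSamples array", nm))
    if (dim(a)[3] != object@mcmc@nSamples)
      return(sprintf("%s sample count disagrees with MCMC settings", nm))
  }
  TRUE
})

#' EigenSummary: eigenanalysis of a covariance matrix
#'
#' @slot values eigenvalues sorted in decreasing order.
#' @slot vectors unit eigenvectors (columns), sign convention: the
#'   largest-magnitude loading of each vector is positive.
#' @slot proportions values / sum(values).
#' @slot traitNames trait names.
#' @export
setClass("EigenSummary", representation(
  values = "numeric", vectors = "matrix", proportions = "numeric",
  traitNames = "character"))

setValidity("EigenSummary", function(object) {
  V <- object@vectors
  if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-6)
    return("eigenvectors must be orthonormal")
  if (is.unsorted(rev(object@values))) return("eigenvalues must be sorted")
  if (abs(sum(object@proportions) - 1) > 1e-6 && sum(object@values) > 0)
    return("variance proportions must sum to 1")
  TRUE
})

#' DirectionVector: a named direction in trait space
#'
#' A plasticity vector (native-environment mean minus novel-environment
#' mean), a selection gradient, or a species-difference (native-phenotype)
#' vector, carrying its context labels. `unitVector()` returns the normalized
#' direction; a zero vector is flagged degenerate and cannot be normalized.
#'
#' @slot vector the raw p-vector.
#' @slot kind one of "plasticity", "selection", "native-difference".
#' @slot labels named character vector of context labels (species, from, to).
#' @slot degenerate TRUE when the raw vector is (numerically) zero.
#' @export
setClass("DirectionVector", representation(
  vector = "numeric", kind = "character", labels = "character",
  degenerate = "logical"))

setValidity("DirectionVector", function(object) {
  if (any(!is.finite(object@vector))) return("entries must be finite")
  TRUE
})

#' TensorResult: genetic covariance tensor of a set of G-matrices
#'
#' Eigenanalysis of the S-matrix — the covariance matrix of the vectorized
#' unique elements of m G-matrices (off-diagonals weighted by sqrt(2) so the
#' Euclidean inner product of vectors equals the Frobenius inner product of
#' matrices). Eigenvectors of S, rearranged into symmetric matrices, are the
#' eigentensors: independent axes of variation among the G-matrices. The
#' coordinate of matrix G_i on eigentensor E_k is the Frobenius inner product
#' <G_i, E_k>; across the m matrices the coordinates on E_k have variance
#' equal to the k-th eigenvalue of S.
#'
#' @slot S q x q S-matrix (q = p(p+1)/2); the posterior mean S when built
#'   from posterior draws.
#' @slot values eigenvalues of S (decreasing).
#' @slot tensors list of symmetric p x p eigentensors, orthonormal under the
#'   Frobenius inner product.
#' @slot coordinates m x k matrix of coordinates (posterior means when built
#'   from draws).
#' @slot coordinateDraws m x k x nDraws array of per-draw coordinates, or a
#'   0-length array for point inputs.
#' @slot matrixLabels labels of the m input matrices.
#' @slot nullValues nSim x k matrix of null eigenvalues (filled by
#'   `nullTensor`), else 0-row matrix.
#' @slot significant logical per eigentensor (NA before `nullTensor`).
#' @export
setClass("TensorResult", representation(
  S = "matrix", values = "numeric", tensors = "list",
  coordinates = "matrix", coordinateDraws = "array",
  matrixLabels = "character", nullValues = "matrix",
  significant = "logical"))

setValidity("TensorResult", function(object) {
  k <- length(object@tensors)
  if (k >= 2) {
    for (a in seq_len(k - 1)) {
      fr <- sum(object@tensors[[a]] * object@tensors[[a + 1]])
      if (abs(fr) > 1e-6) return("eigentensors must be Frobenius-orthogonal")
    }
  }
  TRUE
})

#' ProjectionResult: posterior/bootstrap draws of a projection through G
#'
#' Distribution of (v' G v) / lambda_max — the genetic variance in direction
#' v as a proportion of the maximum genetic variance available — over
#' posterior draws of G and (optionally) bootstrap draws of v.
#'
#' @slot draws numeric vector of proportion draws, each in [0, 1].
#' @slot label what was projected through what.
#' @export
setClass("ProjectionResult",
         representation(draws = "numeric", label = "character"))

setValidity("ProjectionResult", function(object) {
  if (any(object@draws < -1e-9 | object@draws > 1 + 1e-9))
    return("projection draws must lie in [0, 1]")
  TRUE
})

#' SelectionGradientResult: viability selection gradient from logistic
#' regression
#'
#' Multiple logistic regression of binary survival on all traits jointly
#' (beta = P^-1 s: the multivariate fit supplies the phenotypic-covariance
#' adjustment). Coefficients are reported on the logit scale, the probability
#' scale (logit coefficients times the mean of fitted p(1-p), the
#' average-gradient transform), and the relative-fitness scale (probability
#' scale divided by mean survival); the unit-length direction of the
#' relative-scale vector estimates the direction of selection.
#'
#' @slot logitScale,probScale,relScale named coefficient vectors (traits
#'   only, no intercept).
#' @slot unit unit-length direction of selection.
#' @slot meanSurvival mean survival among measured individuals.
#' @slot wald per-trait Wald chi-square statistics and p-values (data.frame).
#' @slot n number of individuals (or families) used.
#' @slot labels context labels.
#' @export
setClass("SelectionGradientResult", representation(
  logitScale = "numeric", probScale = "numeric", relScale = "numeric",
  unit = "numeric", meanSurvival = "numeric", wald = "data.frame",
  n = "integer", labels = "character"))

setValidity("SelectionGradientResult", function(object) {
  if (abs(sqrt(sum(object@unit^2)) - 1) > 1e-6)
    return("unit direction must have norm 1")
  if (object@meanSurvival <= 0 || object@meanSurvival >= 1)
    return("mean survival must lie in (0, 1)")
  TRUE
})

#' DMatrixResult: covariance of group mean phenotypes
#'
#' D summarizes divergence of mean multivariate phenotypes among groups
#' (species x environment); its leading axes d_max and d_2 are the main
#' directions of mean-phenotype change, and group scores are the centered
#' means projected on those axes.
#'
#' @slot D p x p among-group-mean covariance matrix (denominator
#'   n_groups - 1).
#' @slot eigen EigenSummary of D.
#' @slot scores n_groups x p matrix of group scores on the axes.
#' @slot groupLabels labels of the groups.
#' @export
setClass("DMatrixResult", representation(
  D = "matrix", eigen = "EigenSummary", scores = "matrix",
  groupLabels = "character"))
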