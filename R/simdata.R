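#' @include AllGenerics.R
NULL

#' Create a synthetic breeding-design configuration
#'
#' Defaults describe the study conditions the generator emulates: 3 x 3
#' full-factorial sire x dam crossing blocks (12 blocks), offspring of every
#' family planted at four elevations (25 seeds per family per elevation),
#' five mean-standardized leaf traits, environment-specific sire-level
#' covariance (G x E), a shared dam covariance, block variance, and
#' environment-specific residual covariance and trait means, plus
#' trait-dependent logistic survival, random pre-measurement mortality and
#' cross failure (family dropout).
#'
#' On the mean-standardized scale the default variance components are
#' sire 0.05, dam 0.05, block 0.02 and residual 0.4 per trait (sire
#' (co)variances are one quarter of the additive genetic (co)variances, so
#' this corresponds to evolvabilities of roughly 20% of the squared mean —
#' generous but within the range reported for leaf morphology). Default trait
#' means shift by about +/-12% of the grand mean across the elevation
#' gradient, alternating in sign across traits so plasticity is genuinely
#' multivariate.
#'
#' @param nBlocks number of crossing blocks (default 12).
#' @param siresPerBlock,damsPerBlock block dimensions (default 3 x 3).
#' @param lastBlockSires,lastBlockDams size of the final block when smaller
#'   (default NA = same as the rest).
#' @param environments ordered environment labels.
#' @param offspringPerFamilyPerEnv seeds per family per environment.
#' @param traitNames trait names (length p).
#' @param mu list of per-environment trait-mean vectors (default: plastic
#'   means around 1).
#' @param SigmaSire per-environment sire covariance; a single matrix is
#'   recycled to all environments.
#' @param SigmaDam dam-within-sire covariance matrix.
#' @param sigma2Block scalar block variance.
#' @param SigmaResid per-environment residual covariance; single matrix
#'   recycled.
#' @param rhoGE cross-environment correlation of sire effects (default 0.5).
#' @param betaSurvival list per environment of `list(intercept=, beta=)`;
#'   a single such list is recycled. Default: intercept 0.5 and coefficient
#'   1 on the first trait (directional viability selection).
#' @param premeasurementMortality probability of death before measurement
#'   (default 0.3).
#' @param mortalityBeta optional trait-dependence of pre-measurement
#'   mortality (default zero vector = random with respect to phenotype).
#' @param familyDropout probability a cross fails (default 0.13, matching
#'   realized family counts of roughly 94 out of 108 crosses).
#' @param species species label for generated rows.
#' @param seed master seed.
#' @return a validated [SimConfig-class] object.
#' @export
simConfig <- function(nBlocks = 12L, siresPerBlock = 3L, damsPerBlock = 3L,
                      lastBlockSires = NA_integer_,
                      lastBlockDams = NA_integer_,
                      environments = c("elev500", "elev1000", "elev1500",
                                       "elev2000"),
                      offspringPerFamilyPerEnv = 25L,
                      traitNames = c("complexity", "indent_width",
                                     "indent_number", "SLA", "flavonol"),
                      mu = NULL, SigmaSire = NULL, SigmaDam = NULL,
                      sigma2Block = 0.02, SigmaResid = NULL, rhoGE = 0.5,
                      betaSurvival = NULL, premeasurementMortality = 0.3,
                      mortalityBeta = NULL, familyDropout = 0.13,
                      species = "sp_A", seed = 1L) {
  p <- length(traitNames)
  ne <- length(environments)
  if (nBlocks < 1 || siresPerBlock < 1 || damsPerBlock < 1 ||
      offspringPerFamilyPerEnv < 1)
    stop("design counts must be positive integers")
  if (is.null(mu)) {
    shift <- 0.08 * (seq_len(ne) - (ne + 1) / 2)   # plasticity across envs
    sgn <- rep_len(c(1, -1), p)
    mu <- lapply(shift, function(s) setNames(1 + s * sgn, traitNames))
  }
  expandMat <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.matrix(x)) x <- rep(list(x), ne)
    x
  }
  SigmaSire <- expandMat(SigmaSire, diag(0.05, p))
  SigmaResid <- expandMat(SigmaResid, diag(0.4, p))
  if (is.null(SigmaDam)) SigmaDam <- diag(0.05, p)
  if (is.null(betaSurvival))
    betaSurvival <- list(intercept = 0.5,
                         beta = c(1, rep(0, p - 1)))
  if (!is.null(betaSurvival$intercept))  # single spec recycled to all envs
    betaSurvival <- rep(list(betaSurvival), ne)
  if (is.null(mortalityBeta)) mortalityBeta <- rep(0, p)
  new("SimConfig", nBlocks = as.integer(nBlocks),
      siresPerBlock = as.integer(siresPerBlock),
      damsPerBlock = as.integer(damsPerBlock),
      lastBlockSires = as.integer(lastBlockSires),
      lastBlockDams = as.integer(lastBlockDams),
      environments = environments,
      offspringPerFamilyPerEnv = as.integer(offspringPerFamilyPerEnv),
      traitNames = traitNames, mu = mu, SigmaSire = SigmaSire,
      SigmaDam = SigmaDam, sigma2Block = sigma2Block,
      SigmaResid = SigmaResid, rhoGE = rhoGE, betaSurvival = betaSurvival,
      premeasurementMortality = premeasurementMortality,
      mortalityBeta = mortalityBeta, familyDropout = familyDropout,
      species = species, seed = as.integer(seed))
}

#' Build the crossing-design pedigree
#'
#' Full-factorial sire x dam blocks: each block contains
#' `siresPerBlock * damsPerBlock` families; sires and dams are never reused
#' across blocks. The final block may be smaller (`lastBlockSires` x
#' `lastBlockDams`). Family dropout is applied later, by `simulateTraits`.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `block_id`, `sire_id`, `dam_id`,
#'   `family_id`.
#' @export
buildPedigree <- function(config) {
  validObject(config)
  nb <- config@nBlocks
  rows <- vector("list", nb)
  sireCounter <- 0L; damCounter <- 0L
  for (b in seq_len(nb)) {
    ns <- config@siresPerBlock; nd <- config@damsPerBlock
    if (b == nb && !is.na(config@lastBlockSires)) ns <- config@lastBlockSires
    if (b == nb && !is.na(config@lastBlockDams)) nd <- config@lastBlockDams
    sires <- sprintf("S%03d", sireCounter + seq_len(ns))
    dams <- sprintf("D%03d", damCounter + seq_len(nd))
    sireCounter <- sireCounter + ns; damCounter <- damCounter + nd
    g <- expand.grid(sire_id = sires, dam_id = dams,
                     stringsAsFactors = FALSE)
    g$block_id <- sprintf("B%02d", b)
    rows[[b]] <- g
  }
  ped <- do.call(rbind, rows)
  ped$family_id <- paste(ped$sire_id, ped$dam_id, sep = "x")
  ped[, c("block_id", "sire_id", "dam_id", "family_id")]
}

# Joint draw of one sire's effects across environments: block covariance with
# SigmaSire[[e]] on the diagonal blocks and rho * L_e L_f' off-diagonal,
# i.e. Lb (R_rho x I_p) Lb' with Lb = blockdiag(sqrt(SigmaSire[[e]])).
# PSD whenever the equicorrelation matrix R_rho is PSD.
sireEffectCov <- function(SigmaSire, rho) {
  ne <- length(SigmaSire)
  p <- nrow(SigmaSire[[1]])
  Lb <- matrix(0, ne * p, ne * p)
  for (e in seq_len(ne)) {
    i <- (e - 1) * p + seq_len(p)
    Lb[i, i] <- matSqrt(SigmaSire[[e]])
  }
  R <- matrix(rho, ne, ne); diag(R) <- 1
  Lb %*% (R %x% diag(p)) %*% t(Lb)
}

#' Simulate trait values for a pedigree
#'
#' Generative counterpart of the nested half-sib mixed model: each
#' offspring's trait vector is mu(environment) + sire effect + dam effect +
#' block effect + residual. Sire effects are drawn jointly across
#' environments from the per-environment sire covariances with
#' cross-environment correlation `rhoGE` (so G can genuinely differ across
#' environments); dam effects are drawn once per dam and shared across
#' environments; block effects are independent per block x environment.
#' Family dropout removes whole crosses before seeds are produced.
#'
#' @param pedigree output of [buildPedigree()].
#' @param config the [SimConfig-class] used to build it.
#' @return a [PhenotypeTable-class] with `emerged = measured = 1` and
#'   `survived = NA` (see [simulateSurvival()]).
#' @export
simulateTraits <- function(pedigree, config) {
  validObject(config)
  p <- length(config@traitNames)
  ne <- length(config@environments)
  for (m in config@mu)
    if (length(m) != p) stop("mu dimension does not match trait count")

  set.seed(deriveSeed(config@seed, "dropout"))
  keep <- runif(nrow(pedigree)) >= config@familyDropout
  ped <- pedigree[keep, , drop = FALSE]
  if (!nrow(ped)) stop("all families dropped out; lower familyDropout")

  set.seed(deriveSeed(config@seed, "traits"))
  sires <- unique(ped$sire_id)
  dams <- unique(ped$dam_id)
  blocks <- unique(ped$block_id)

  # sire effects: nSire x (ne * p), jointly correlated across environments
  J <- sireEffectCov(config@SigmaSire, config@rhoGE)
  sEff <- mvrnorm(length(sires), mu = rep(0, ne * p), Sigma = J)
  sEff <- matrix(sEff, nrow = length(sires))
  rownames(sEff) <- sires
  dEff <- mvrnorm(length(dams), mu = rep(0, p), Sigma = config@SigmaDam)
  dEff <- matrix(dEff, nrow = length(dams))
  rownames(dEff) <- dams
  bEff <- matrix(rnorm(length(blocks) * ne * p,
                       sd = sqrt(config@sigma2Block)),
                 nrow = length(blocks))
  rownames(bEff) <- blocks

  noff <- config@offspringPerFamilyPerEnv
  out <- vector("list", ne)
  for (e in seq_len(ne)) {
    env <- config@environments[e]
    idx <- rep(seq_len(nrow(ped)), each = noff)
    n <- length(idx)
    cols <- (e - 1) * p + seq_len(p)
    E <- mvrnorm(n, mu = rep(0, p), Sigma = config@SigmaResid[[e]])
    E <- matrix(E, nrow = n)
    tr <- matrix(config@mu[[e]], n, p, byrow = TRUE) +
      sEff[ped$sire_id[idx], cols, drop = FALSE] +
      dEff[ped$dam_id[idx], , drop = FALSE] +
      bEff[ped$block_id[idx], cols, drop = FALSE] +
      E
    colnames(tr) <- config@traitNames
    d <- data.frame(
      individual_id = sprintf("%s_%s_%s_%04d", config@species, env,
                              ped$family_id[idx],
                              sequence(rep(noff, nrow(ped)))),
      sire_id = ped$sire_id[idx], dam_id = ped$dam_id[idx],
      block_id = ped$block_id[idx], species = config@species,
      environment = env, stringsAsFactors = FALSE)
    d <- cbind(d, as.data.frame(tr))
    d$emerged <- 1L; d$measured <- 1L; d$survived <- NA_integer_
    out[[e]] <- d
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  new("PhenotypeTable", data = d, traitNames = config@traitNames)
}

#' Simulate survival and pre-measurement mortality
#'
#' Survival is Bernoulli with logit probability
#' `intercept + beta . (traits - context mean)` using the environment's
#' coefficients. Pre-measurement mortality then marks individuals unmeasured
#' (traits erased, survived set to 0): uniformly at random by default, or
#' trait-dependent when `mortalityBeta` is nonzero (logit offset on the
#' latent traits), to study the bias that phenotype-selective early
#' mortality could induce.
#'
#' @param table a [PhenotypeTable-class] from [simulateTraits()].
#' @param config the same [SimConfig-class].
#' @return the table with `survived` and `measured` filled in.
#' @export
simulateSurvival <- function(table, config) {
  d <- as.data.frame(table)
  tn <- traitNames(table)
  p <- length(tn)
  set.seed(deriveSeed(config@seed, "survival"))
  for (e in seq_along(config@environments)) {
    env <- config@environments[e]
    rows <- which(d$environment == env)
    if (!length(rows)) next
    tr <- as.matrix(d[rows, tn, drop = FALSE])
    ctr <- sweep(tr, 2, colMeans(tr))
    bs <- config@betaSurvival[[e]]
    eta <- bs$intercept + as.vector(ctr %*% bs$beta)
    d$survived[rows] <- rbinom(length(rows), 1, plogis(eta))
    # pre-measurement mortality: those individuals die before traits are
    # taken, so they are unmeasured and did not survive
    pm <- config@premeasurementMortality
    if (pm > 0) {
      if (any(config@mortalityBeta != 0)) {
        pdie <- plogis(qlogis(pm) + as.vector(ctr %*% config@mortalityBeta))
      } else {
        pdie <- rep(pm, length(rows))
      }
      dead <- runif(length(rows)) < pdie
      d$measured[rows][dead] <- 0L
      d$survived[rows][dead] <- 0L
      d[rows[dead], tn] <- NA_real_
    }
  }
  new("PhenotypeTable", data = d, traitNames = tn)
}

#' Simulate a complete breeding-design dataset
#'
#' Convenience wrapper: [buildPedigree()] then [simulateTraits()] then
#' [simulateSurvival()]. Identical seeds reproduce identical tables.
#'
#' @param config a [SimConfig-class].
#' @return a [PhenotypeTable-class].
#' @export
simulateDataset <- function(config) {
  simulateSurvival(simulateTraits(buildPedigree(config), config), config)
}

#' Combine phenotype tables (e.g. two species)
#'
#' @param ... PhenotypeTable objects with identical trait names.
#' @return a single [PhenotypeTable-class].
#' @export
combinePhenotypes <- function(...) {
  tabs <- list(...)
  tn <- traitNames(tabs[[1]])
  for (t in tabs) if (!identical(traitNames(t), tn))
    stop("trait names differ between tables")
  new("PhenotypeTable",
      data = do.call(rbind, lapply(tabs, as.data.frame)), traitNames = tn)
}

matToRows <- function(M) lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
rowsToMat <- function(L) do.call(rbind, lapply(L, as.numeric))

#' Write a simulation configuration as YAML
#'
#' @param config a [SimConfig-class].
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  x <- list()
  for (nm in c("nBlocks", "siresPerBlock", "damsPerBlock", "environments",
               "offspringPerFamilyPerEnv", "traitNames", "sigma2Block",
               "rhoGE", "premeasurementMortality", "mortalityBeta",
               "familyDropout", "species", "seed"))
    x[[nm]] <- slot(config, nm)
  if (!is.na(config@lastBlockSires)) x$lastBlockSires <- config@lastBlockSires
  if (!is.na(config@lastBlockDams)) x$lastBlockDams <- config@lastBlockDams
  # named lists so YAML preserves the trait names of each mean vector
  x$mu <- lapply(config@mu, as.list)
  x$SigmaSire <- lapply(config@SigmaSire, matToRows)
  x$SigmaDam <- matToRows(config@SigmaDam)
  x$SigmaResid <- lapply(config@SigmaResid, matToRows)
  x$betaSurvival <- lapply(config@betaSurvival, function(b)
    list(intercept = b$intercept, beta = as.numeric(b$beta)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Inverse of [writeSimConfig()].
#'
#' @param path YAML file written by [writeSimConfig()].
#' @return a validated [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$SigmaSire <- lapply(x$SigmaSire, rowsToMat)
  x$SigmaDam <- rowsToMat(x$SigmaDam)
  x$SigmaResid <- lapply(x$SigmaResid, rowsToMat)
  x$mu <- lapply(x$mu, function(m) {
    v <- unlist(m)
    setNames(as.numeric(v), names(v))
  })
  x$betaSurvival <- lapply(x$betaSurvival, function(b)
    list(intercept = b$intercept, beta = as.numeric(b$beta)))
  do.call(simConfig, x)
}
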