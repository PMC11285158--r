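#' @include AllGenerics.R
NULL

#' MCMC settings for the half-sib Gibbs sampler
#'
#' Desk-scale defaults (burn-in 5,000, thin 10, 1,000 saved draws) mix well
#' for balanced half-sib designs; field-scale settings (burn-in 150,000,
#' thin 1,500, 2,000 draws) are one call away for production analyses.
#'
#' @param nBurnin burn-in iterations.
#' @param thin thinning interval.
#' @param nSamples saved posterior draws.
#' @param seed RNG seed.
#' @return an [MCMCSettings-class].
#' @export
mcmcSettings <- function(nBurnin = 5000L, thin = 10L, nSamples = 1000L,
                         seed = 1L) {
  new("MCMCSettings", nBurnin = as.integer(nBurnin), thin = as.integer(thin),
      nSamples = as.integer(nSamples), seed = as.integer(seed))
}

# Default inverse-Wishart prior: df = p + 1 and scale matrix equal to the
# mean phenotypic variance divided by the number of variance components,
# times the identity (the usual weakly-informative heuristic for
# variance-component models). Configurable via `prior`.
defaultPrior <- function(Y, blockAsRandom = TRUE) {
  p <- ncol(Y)
  nComp <- if (blockAsRandom) 4 else 3
  v <- mean(apply(Y, 2, var))
  if (!is.finite(v) || v <= 0) v <- 1e-6
  S <- diag(v / nComp, p)
  list(df = p + 1, scaleSire = S, scaleDam = S, scaleBlock = S,
       scaleResid = S)
}

#' Fit the multivariate nested half-sib mixed model by Gibbs sampling
#'
#' Model: trait vector = mu + sire + dam(sire) + block + residual, with all
#' traits analyzed jointly (full covariance matrices for every component,
#' not trait-by-trait). Conditionally conjugate inverse-Wishart updates for
#' the four covariance components; flat prior on mu. Between-sire
#' (co)variances estimate one quarter of the additive genetic (co)variances;
#' see [extractG()].
#'
#' @param table a [PhenotypeTable-class]; must contain exactly one species x
#'   environment context (or pass `species` / `environment` to subset).
#'   Unmeasured individuals are dropped.
#' @param species,environment optional context filters.
#' @param mcmc an [MCMCSettings-class].
#' @param prior NULL for the default (inverse-Wishart, df = p + 1, scale =
#'   mean phenotypic variance / number of components * identity), or a list
#'   with `df`, `scaleSire`, `scaleDam`, `scaleBlock`, `scaleResid`.
#' @param blockAsRandom treat block as a random effect with its own
#'   covariance (default); FALSE gives flat-prior (fixed-effect-like) block
#'   effects.
#' @return a [GPosterior-class].
#' @export
fitHalfsib <- function(table, species = NULL, environment = NULL,
                       mcmc = mcmcSettings(), prior = NULL,
                       blockAsRandom = TRUE) {
  tab <- subsetContext(table, species, environment, measuredOnly = TRUE)
  d <- as.data.frame(tab)
  if (!nrow(d)) stop("no measured individuals in the requested context")
  if (length(unique(d$species)) > 1 || length(unique(d$environment)) > 1)
    stop("table spans several contexts; fit one species x environment ",
         "at a time")
  tn <- traitNames(tab)
  p <- length(tn)
  Y <- as.matrix(d[, tn, drop = FALSE])
  storage.mode(Y) <- "double"

  sireLev <- sort(unique(d$sire_id))
  damLev <- sort(unique(paste(d$sire_id, d$dam_id, sep = "\r")))
  blockLev <- sort(unique(d$block_id))
  if (length(sireLev) < 2)
    stop("fewer than 2 sires: sire variance is inestimable")
  sire <- match(d$sire_id, sireLev) - 1L
  dam <- match(paste(d$sire_id, d$dam_id, sep = "\r"), damLev) - 1L
  block <- match(d$block_id, blockLev) - 1L

  if (is.null(prior)) prior <- defaultPrior(Y, blockAsRandom)
  if (prior$df <= p - 1)
    stop("prior degrees of freedom must exceed p - 1")
  for (nm in c("scaleSire", "scaleDam", "scaleBlock", "scaleResid"))
    if (!isPSD(prior[[nm]]) ||
        min(eigen(prior[[nm]], symmetric = TRUE,
                  only.values = TRUE)$values) <= 0)
      stop("prior scale matrix '", nm, "' must be symmetric positive definite")

  set.seed(mcmc@seed)
  fit <- .gibbs_halfsib(Y, sire, dam, block,
                        prior$df, prior$scaleSire,
                        prior$df, prior$scaleDam,
                        prior$df, prior$scaleBlock,
                        prior$df, prior$scaleResid,
                        mcmc@nBurnin, mcmc@thin, mcmc@nSamples,
                        blockAsRandom)
  dn <- list(tn, tn, NULL)
  for (nm in c("sigma_sire", "sigma_dam", "sigma_block", "sigma_resid"))
    dimnames(fit[[nm]]) <- dn
  new("GPosterior",
      species = as.character(d$species[1]),
      environment = as.character(d$environment[1]), traitNames = tn,
      sigmaSire = fit$sigma_sire, sigmaDam = fit$sigma_dam,
      sigmaBlock = fit$sigma_block, sigmaResid = fit$sigma_resid,
      mu = fit$mu,
      effects = list(sire = fit$eff_sire, dam = fit$eff_dam,
                     block = fit$eff_block, mu = as.vector(fit$eff_mu)),
      modelData = list(Y = Y, sire = sire, dam = dam, block = block,
                       sireLevels = sireLev, damLevels = damLev,
                       blockLevels = blockLev),
      mcmc = mcmc)
}

#' Extract posterior G draws
#'
#' G is defined from the sire covariance component. With `scale = 1`
#' (default) G is the sire (co)variance matrix itself, the scale on which
#' results are reported; `scale = 4` converts to the full
#' additive-genetic-variance scale (between-sire variance is one quarter of
#' the additive variance under the half-sib design). All proportional
#' quantities downstream (eigen-proportions, angles, projection ratios) are
#' identical under either scale.
#'
#' @param posterior a [GPosterior-class].
#' @param scale 1 or 4.
#' @return p x p x nSamples array of G draws.
#' @export
extractG <- function(posterior, scale = 1) {
  if (!scale %in% c(1, 4)) stop("scale must be 1 or 4")
  posterior@sigmaSire * scale
}

# lag-1 autocorrelation and a standard initial-monotone ESS for one chain
chainStats <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(c(lag1 = 0, ess = n))
  ac <- acf(x, lag.max = min(n - 1, 50), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)
  upto <- if (length(pos)) min(pos) - 1 else length(ac)
  ess <- n / (1 + 2 * sum(ac[seq_len(upto)]))
  c(lag1 = ac[1], ess = min(ess, n))
}

#' Chain mixing diagnostics
#'
#' Per-element lag-1 autocorrelation of the thinned draws and effective
#' sample size for every unique element of every covariance component; an
#' element passes when |lag-1 autocorrelation| < `threshold` (default 0.05,
#' the conventional bar for well-thinned chains).
#'
#' @param posterior a [GPosterior-class], or a matrix whose columns are
#'   scalar chains.
#' @param threshold pass/fail bar on |lag-1 autocorrelation|.
#' @return data.frame with columns `component`, `element`, `lag1`, `ess`,
#'   `pass`; deterministic given the draws.
#' @export
diagnoseChain <- function(posterior, threshold = 0.05) {
  if (is.matrix(posterior)) {
    if (nrow(posterior) < 100) stop("need at least 100 draws to diagnose")
    st <- t(apply(posterior, 2, chainStats))
    nm <- colnames(posterior)
    if (is.null(nm)) nm <- paste0("chain", seq_len(ncol(posterior)))
    return(data.frame(component = "chain", element = nm,
                      lag1 = st[, "lag1"], ess = st[, "ess"],
                      pass = abs(st[, "lag1"]) < threshold,
                      row.names = NULL))
  }
  stopifnot(is(posterior, "GPosterior"))
  if (nDraws(posterior) < 100) stop("need at least 100 draws to diagnose")
  tn <- posterior@traitNames
  p <- length(tn)
  comps <- list(sire = posterior@sigmaSire, dam = posterior@sigmaDam,
                block = posterior@sigmaBlock, resid = posterior@sigmaResid)
  rows <- list()
  for (cn in names(comps)) {
    a <- comps[[cn]]
    for (i in seq_len(p)) for (j in seq_len(i)) {
      st <- chainStats(a[i, j, ])
      rows[[length(rows) + 1]] <- data.frame(
        component = cn, element = paste(tn[i], tn[j], sep = ":"),
        lag1 = st["lag1"], ess = st["ess"],
        pass = abs(st["lag1"]) < threshold, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Randomize offspring among sires within blocks
#'
#' Null-hypothesis randomization for the sire variance: within each crossing
#' block, the (sire, dam) assignments are permuted among the offspring rows,
#' so block differences are maintained while any offspring-sire association
#' is destroyed. Block sizes and the multiset of family sizes within each
#' block are preserved exactly.
#'
#' @param table a [PhenotypeTable-class] (one context).
#' @param seed RNG seed.
#' @return the randomized [PhenotypeTable-class].
#' @export
randomizeOffspring <- function(table, seed = 1L) {
  d <- as.data.frame(table)
  set.seed(deriveSeed(seed, "randomize-offspring"))
  for (b in unique(d$block_id)) {
    rows <- which(d$block_id == b)
    perm <- sample(length(rows))
    d$sire_id[rows] <- d$sire_id[rows][perm]
    d$dam_id[rows] <- d$dam_id[rows][perm]
  }
  new("PhenotypeTable", data = d, traitNames = traitNames(table))
}

#' Randomization test for elements of G
#'
#' Compares each element's observed posterior mean to the distribution of
#' posterior means obtained by refitting the model to data with offspring
#' randomized among sires within blocks. Because the sampler constrains
#' variances to be positive, exceedance over this null — rather than overlap
#' with zero — is the appropriate significance criterion. One-sided: an
#' element is significant when its observed posterior mean exceeds the
#' (1 - alpha) quantile of its null posterior means. Off-diagonal elements
#' are tested on |value| (their null is centered on zero).
#'
#' @param table one-context [PhenotypeTable-class].
#' @param nPerm number of randomizations (the field-scale analysis uses
#'   1,000; small values give unstable null quantiles and warn).
#' @param alpha significance level (default 0.05).
#' @param mcmc [MCMCSettings-class] for the observed fit.
#' @param mcmcNull reduced settings for the null refits (default: the
#'   observed settings).
#' @param observed optional pre-computed [GPosterior-class] for the observed
#'   data.
#' @param seed RNG seed for the randomizations.
#' @param ... passed to [fitHalfsib()].
#' @return list: `observedMean` (G posterior mean), `nullMeans`
#'   (nPerm x p x p array), `significant` (logical p x p), `pvalues`.
#' @export
nullGTest <- function(table, nPerm = 1000L, alpha = 0.05,
                      mcmc = mcmcSettings(), mcmcNull = mcmc,
                      observed = NULL, seed = 1L, ...) {
  if (nPerm < 1) stop("nPerm must be positive")
  if (nPerm < 20) warning("nPerm < 20: null quantiles are unstable")
  if (is.null(observed)) observed <- fitHalfsib(table, mcmc = mcmc, ...)
  obsMean <- posteriorMean(observed, "sire")
  p <- nrow(obsMean)
  nullMeans <- array(NA_real_, c(nPerm, p, p))
  for (r in seq_len(nPerm)) {
    rt <- randomizeOffspring(table, seed = deriveSeed(seed, paste0("perm", r)))
    f <- fitHalfsib(rt, mcmc = new("MCMCSettings",
                                   nBurnin = mcmcNull@nBurnin,
                                   thin = mcmcNull@thin,
                                   nSamples = mcmcNull@nSamples,
                                   seed = deriveSeed(seed,
                                                     paste0("permfit", r))),
                    ...)
    nullMeans[r, , ] <- posteriorMean(f, "sire")
  }
  sig <- matrix(FALSE, p, p, dimnames = dimnames(obsMean))
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(obsMean))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    obs <- if (i == j) obsMean[i, j] else abs(obsMean[i, j])
    nul <- if (i == j) nullMeans[, i, j] else abs(nullMeans[, i, j])
    pv[i, j] <- (1 + sum(nul >= obs)) / (nPerm + 1)
    sig[i, j] <- obs > quantile(nul, 1 - alpha)
  }
  list(observedMean = obsMean, nullMeans = nullMeans, significant = sig,
       pvalues = pv)
}

#' Export posterior G draws to a directory
#'
#' Writes one plain-text matrix file per posterior draw of the chosen
#' component plus a JSON summary (posterior means, 95% HPD intervals per
#' element, and chain diagnostics), so downstream comparisons can consume
#' fitted posteriors without refitting.
#'
#' @param posterior a [GPosterior-class].
#' @param dir output directory (created if needed).
#' @param component which covariance component to export (default "sire",
#'   i.e. G).
#' @param scale scale factor for the sire component (see [extractG()]).
#' @return `dir`, invisibly.
#' @export
exportPosterior <- function(posterior, dir, component = "sire", scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- if (component == "sire") extractG(posterior, scale) else
    slot(posterior, paste0("sigma", toupper(substring(component, 1, 1)),
                           substring(component, 2)))
  n <- dim(a)[3]
  for (i in seq_len(n))
    write.table(a[, , i], file.path(dir, sprintf("draw_%05d.txt", i)),
                row.names = FALSE, col.names = FALSE)
  tn <- posterior@traitNames
  p <- length(tn)
  hpd <- matrix(NA_real_, p * p, 4)
  k <- 0
  elem <- character(p * p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    k <- k + 1
    h <- hpdInterval(a[i, j, ])
    hpd[k, ] <- c(i, j, h)
    elem[k] <- paste(tn[i], tn[j], sep = ":")
  }
  summary <- list(
    context = contextLabel(posterior), traitNames = tn,
    component = component, scale = scale, nDraws = n,
    posteriorMean = apply(a, c(1, 2), mean),
    hpd = data.frame(element = elem, row = hpd[, 1], col = hpd[, 2],
                     lower = hpd[, 3], upper = hpd[, 4]),
    diagnostics = diagnoseChain(posterior))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  invisible(dir)
}

#' Read a directory of posterior G draws
#'
#' Inverse of [exportPosterior()]: reads `draw_*.txt` matrix files into a
#' p x p x n array suitable for [covarianceTensor()], [anglePosterior()] and
#' [projectPosterior()].
#'
#' @param dir directory written by [exportPosterior()].
#' @return p x p x n array of draws.
#' @export
readGDraws <- function(dir) {
  files <- sort(list.files(dir, pattern = "^draw_\\d+\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no draw files found in ", dir)
  first <- as.matrix(read.table(files[1]))
  a <- array(NA_real_, c(nrow(first), ncol(first), length(files)))
  a[, , 1] <- first
  for (i in seq_along(files)[-1])
    a[, , i] <- as.matrix(read.table(files[i]))
  a
}
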