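# Bayesian half-sib mixed model

test_that("posterior sire variance agrees with the closed-form ANOVA estimator", {
  # balanced single-block factorial with well-separated components; the
  # nested ANOVA moment estimator (MS_sire - MS_dam) / (d * k) is the oracle
  # (a single block so no sire variance is absorbed by block effects)
  cfg <- quickConfig(p = 1L, nBlocks = 1L, siresPerBlock = 50L,
                     damsPerBlock = 4L, environments = "only",
                     mu = list(only = 10),
                     offspringPerFamilyPerEnv = 8L,
                     SigmaSire = matrix(0.3), SigmaDam = matrix(0.2),
                     sigma2Block = 0, SigmaResid = matrix(0.5), seed = 2L)
  tab <- simulateDataset(cfg)
  d <- as.data.frame(tab)
  k <- 8; nd <- 4
  y <- d$t1
  sireMean <- tapply(y, d$sire_id, mean)
  damMean <- tapply(y, paste(d$sire_id, d$dam_id), mean)
  damSire <- tapply(d$sire_id, paste(d$sire_id, d$dam_id), function(x) x[1])
  msSire <- k * nd * sum((sireMean - mean(y))^2) / (length(sireMean) - 1)
  msDam <- k * sum((damMean - sireMean[damSire])^2) /
    (length(damMean) - length(sireMean))
  anovaSire <- (msSire - msDam) / (nd * k)

  fit <- fitHalfsib(tab, mcmc = mcmcSettings(nBurnin = 1000, thin = 5,
                                             nSamples = 400, seed = 7))
  postSire <- posteriorMean(fit, "sire")[1, 1]
  expect_lt(abs(postSire - anovaSire) / anovaSire, 0.25)
})

test_that("every posterior draw of every component is symmetric PSD", {
  cfg <- quickConfig(seed = 31L)
  tab <- simulateDataset(cfg)
  fit <- fitHalfsib(tab, environment = "native", mcmc = fastMCMC())
  for (nm in c("sire", "dam", "block", "resid")) {
    a <- slot(fit, paste0("sigma",
                          c(sire = "Sire", dam = "Dam", block = "Block",
                            resid = "Resid")[nm]))
    for (i in seq_len(dim(a)[3])) {
      M <- a[, , i]
      expect_lt(max(abs(M - t(M))), 1e-10)
      expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
    }
  }
})

test_that("permuting trait columns permutes the posterior mean G", {
  cfg <- quickConfig(nBlocks = 6L, seed = 13L,
                     SigmaSire = diag(c(0.10, 0.05, 0.02)))
  tab <- simulateDataset(cfg)
  fit <- fitHalfsib(tab, environment = "native",
                    mcmc = mcmcSettings(nBurnin = 500, thin = 2,
                                        nSamples = 500, seed = 9))
  perm <- c(3, 1, 2)
  d <- as.data.frame(tab)
  dPerm <- d
  dPerm[, traitNames(tab)] <- d[, traitNames(tab)[perm]]
  names(dPerm)[match(traitNames(tab), names(dPerm))] <-
    traitNames(tab)  # keep column names, values permuted
  tabPerm <- new("PhenotypeTable", data = dPerm, traitNames = traitNames(tab))
  fitPerm <- fitHalfsib(tabPerm, environment = "native",
                        mcmc = mcmcSettings(nBurnin = 500, thin = 2,
                                            nSamples = 500, seed = 9))
  G <- posteriorMean(fit, "sire")
  GP <- posteriorMean(fitPerm, "sire")
  # equality is distributional: posterior means agree to Monte Carlo error
  expect_lt(max(abs(unname(GP) - unname(G[perm, perm]))), 0.01)
})

test_that("G scale factor is a pure rescaling with identical proportional quantities", {
  cfg <- quickConfig(seed = 17L)
  tab <- simulateDataset(cfg)
  fit <- fitHalfsib(tab, environment = "native", mcmc = fastMCMC(seed = 2))
  g1 <- extractG(fit, scale = 1)
  g4 <- extractG(fit, scale = 4)
  expect_equal(g4, g1 * 4)
  e1 <- eigenG(apply(g1, c(1, 2), mean))
  e4 <- eigenG(apply(g4, c(1, 2), mean))
  expect_equal(e4@values, 4 * e1@values)          # ordering preserved
  expect_equal(e4@proportions, e1@proportions)    # proportions identical
  expect_equal(e4@vectors, e1@vectors)
  v <- c(1, 2, -1)
  expect_equal(projectThroughG(v, apply(g4, c(1, 2), mean)),
               projectThroughG(v, apply(g1, c(1, 2), mean)))
  # trivial numeric example of the scaling itself
  expect_equal(extractG(fit, 4)[, , 1], 4 * fit@sigmaSire[, , 1])
  expect_error(extractG(fit, 2), "scale")
})

test_that("degenerate data collapse the residual toward zero", {
  cfg <- quickConfig(nBlocks = 3L)
  tab <- simulateDataset(cfg)
  d <- as.data.frame(tab)
  d[, traitNames(tab)] <- matrix(rep(c(1, 2, 3), each = nrow(d)), nrow(d))
  const <- new("PhenotypeTable", data = d, traitNames = traitNames(tab))
  fit <- fitHalfsib(const, environment = "native", mcmc = fastMCMC(seed = 5))
  expect_lt(max(diag(posteriorMean(fit, "resid"))), 1e-3)
  expect_lt(max(diag(posteriorMean(fit, "sire"))), 0.05)
})

test_that("fit preconditions are enforced", {
  cfg <- quickConfig()
  tab <- simulateDataset(cfg)
  expect_error(fitHalfsib(tab), "several contexts")
  oneSire <- subsetContext(tab, environment = "native")
  d <- as.data.frame(oneSire)
  d <- d[d$sire_id == d$sire_id[1], ]
  expect_error(fitHalfsib(new("PhenotypeTable", data = d,
                              traitNames = traitNames(tab))),
               "fewer than 2 sires")
  expect_error(fitHalfsib(tab, environment = "native",
                          prior = list(df = 1, scaleSire = diag(3),
                                       scaleDam = diag(3),
                                       scaleBlock = diag(3),
                                       scaleResid = diag(3))),
               "degrees of freedom")
})

test_that("chain diagnostics flag autocorrelated chains and pass independent ones", {
  set.seed(4)
  # 10,000 draws so the Monte Carlo noise of the autocorrelation estimate
  # (sd ~ 0.01) sits well inside the 0.05 bar
  iid <- matrix(rnorm(20000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  rep1 <- diagnoseChain(iid)
  expect_true(all(rep1$pass))
  expect_true(all(abs(rep1$lag1) < 0.05))

  # injected AR(1) with phi = 0.9 must fail
  ar <- as.numeric(stats::filter(rnorm(1000), 0.9, method = "recursive"))
  rep2 <- diagnoseChain(cbind(ar = ar, ok = rnorm(1000)))
  expect_false(rep2$pass[rep2$element == "ar"])
  expect_lt(rep2$ess[rep2$element == "ar"], 200)

  # deterministic given the draws
  expect_identical(diagnoseChain(iid), rep1)
  expect_error(diagnoseChain(iid[1:50, ]), "100 draws")
})

test_that("thinned sampler chains mix below the autocorrelation bar", {
  # variance-component chains decorrelate slowly (hence the heavy thinning
  # the production settings use); at thin = 40 the residual autocorrelation
  # is near zero, and 2,000 saved draws keep the estimate's Monte Carlo
  # noise (~0.02) inside the 0.05 bar for most elements
  cfg <- quickConfig(nBlocks = 12L, environments = "only",
                     mu = list(only = rep(1, 3)),
                     offspringPerFamilyPerEnv = 5L, seed = 23L)
  tab <- simulateDataset(cfg)
  fit <- fitHalfsib(tab, mcmc = mcmcSettings(nBurnin = 1000, thin = 40,
                                             nSamples = 2000, seed = 3))
  rep <- diagnoseChain(fit)
  expect_gt(mean(rep$pass), 0.85)
  expect_lt(stats::median(abs(rep$lag1)), 0.05)
})

test_that("offspring randomization permutes assignments within blocks only", {
  cfg <- quickConfig(nBlocks = 3L, seed = 19L)
  tab <- subsetContext(simulateDataset(cfg), environment = "native")
  rnd <- randomizeOffspring(tab, seed = 7L)
  d <- as.data.frame(tab); r <- as.data.frame(rnd)
  # block sizes unchanged; no row changed block
  expect_identical(r$block_id, d$block_id)
  expect_identical(r$individual_id, d$individual_id)
  # traits untouched, only pedigree assignment moved
  expect_identical(r$t1, d$t1)
  # family-size multiset preserved within each block
  for (b in unique(d$block_id)) {
    expect_equal(sort(table(paste(r$sire_id, r$dam_id)[r$block_id == b])),
                 sort(table(paste(d$sire_id, d$dam_id)[d$block_id == b])),
                 ignore_attr = TRUE)
  }
  # assignments really were shuffled somewhere
  expect_false(identical(r$sire_id, d$sire_id))

  # single-family block: permutation is the identity at assignment level
  one <- as.data.frame(tab)
  one <- one[one$sire_id == one$sire_id[1] & one$dam_id == one$dam_id[1], ]
  oneTab <- new("PhenotypeTable", data = one, traitNames = traitNames(tab))
  rndOne <- randomizeOffspring(oneTab, seed = 3L)
  expect_identical(as.data.frame(rndOne), one)
})

test_that("null randomization test validates its permutation count", {
  cfg <- quickConfig(nBlocks = 2L, offspringPerFamilyPerEnv = 3L)
  tab <- subsetContext(simulateDataset(cfg), environment = "native")
  expect_error(nullGTest(tab, nPerm = 0L), "positive")
  expect_warning(
    nullGTest(tab, nPerm = 2L,
              mcmc = mcmcSettings(nBurnin = 50, thin = 1, nSamples = 50)),
    "unstable")
})

test_that("posterior draws export to plain-text files and read back", {
  cfg <- quickConfig(nBlocks = 3L, seed = 41L)
  tab <- simulateDataset(cfg)
  fit <- fitHalfsib(tab, environment = "native", mcmc = fastMCMC(seed = 6))
  dir <- tempfile("gpost")
  exportPosterior(fit, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  a <- readGDraws(dir)
  expect_equal(a, unname(extractG(fit)), tolerance = 1e-12)
  s <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(s$nDraws, nDraws(fit))
  expect_equal(as.matrix(s$posteriorMean), unname(posteriorMean(fit, "sire")),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(readGDraws(tempfile()), "no draw files")
})
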