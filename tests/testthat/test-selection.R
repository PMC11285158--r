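# direction vectors, projections through G, and selection gradients

test_that("plasticity and native-difference vectors are signed differences", {
  nat <- c(a = 1, b = 1, c = 1, d = 1, e = 1)
  oth <- c(a = 0.8, b = 1.2, c = 1, d = 1, e = 1)
  dv <- plasticityVector(nat, oth)
  expect_equal(rawVector(dv), c(0.2, -0.2, 0, 0, 0))
  expect_false(dv@degenerate)
  # antisymmetry
  expect_equal(rawVector(plasticityVector(oth, nat)), -rawVector(dv))
  # identical means: degenerate, cannot be normalized
  dz <- plasticityVector(nat, nat)
  expect_true(dz@degenerate)
  expect_error(unitVector(dz), "degenerate")
  expect_error(plasticityVector(nat, oth[1:3]), "dimensions differ")

  nd <- nativeDirection(nat, oth, environment = "elev500")
  expect_equal(rawVector(nd), rawVector(dv))
  expect_equal(rawVector(nativeDirection(oth, nat)), -rawVector(nd))
  expect_true(nativeDirection(nat, nat)@degenerate)
})

test_that("projection through G is the bounded proportion of genetic variance", {
  G <- diag(c(0.4, 0.1))
  expect_equal(projectThroughG(c(0, 1), G), 0.25)
  expect_equal(projectThroughG(c(1, 0), G), 1)       # v = g_max
  expect_equal(projectThroughG(c(3, 0), G), 1)       # normalized internally
  # G = I: any direction has the full proportion
  set.seed(6)
  for (p in 2:5) expect_equal(projectThroughG(rnorm(p), diag(p)), 1)
  # eigenvector k gives lambda_k / lambda_max exactly
  for (i in 1:10) {
    R <- randomPSD(4)
    es <- eigenG(R)
    for (k in 1:4)
      expect_lt(abs(projectThroughG(es@vectors[, k], R) -
                      es@values[k] / es@values[1]), 1e-12)
    # arbitrary directions stay in [0, 1]
    v <- rnorm(4)
    pr <- projectThroughG(v, R)
    expect_gte(pr, 0); expect_lte(pr, 1)
    # ratio form is scale invariant
    expect_equal(projectThroughG(v, 7 * R), pr)
  }
  expect_error(projectThroughG(c(0, 0), G), "zero vector")
  expect_error(projectThroughG(c(1, 0), matrix(0, 2, 2)), "lambda_max")
})

test_that("posterior projection handles fixed and distributional inputs", {
  G <- diag(c(0.4, 0.1))
  # fixed v, single G: point mass
  pr <- projectPosterior(c(0, 1), G)
  expect_equal(draws(pr), 0.25)
  # v draws over the eigenvectors: draws in {1, 0.25}
  V <- rbind(c(1, 0), c(0, 1))
  arr <- array(G, c(2, 2, 40))
  pr2 <- projectPosterior(V, arr, pairing = "cross")
  expect_true(all(round(draws(pr2), 10) %in% c(1, 0.25)))
  expect_true(all(draws(pr2) >= 0 & draws(pr2) <= 1))
  expect_error(projectPosterior(matrix(numeric(0), 0, 2), arr), "empty")
  # overlap report
  a <- new("ProjectionResult", draws = runif(200, 0.1, 0.3), label = "a")
  b <- new("ProjectionResult", draws = runif(200, 0.6, 0.9), label = "b")
  expect_false(hpdOverlap(a, b, 0.9)$overlap)
  expect_true(hpdOverlap(a, a, 0.9)$overlap)
})

test_that("selection gradient recovers a known direction and scales correctly", {
  # survival depends only on trait 1: unit direction aligns with e1
  set.seed(15)
  n <- 5000; p <- 5
  X <- MASS::mvrnorm(n, rep(1, p), diag(0.04, p))
  colnames(X) <- paste0("t", 1:p)
  eta <- 1.5 * scale(X[, 1], scale = FALSE)
  s <- rbinom(n, 1, plogis(as.vector(eta)))
  d <- data.frame(individual_id = as.character(1:n), sire_id = "S1",
                  dam_id = "D1", block_id = "B1", species = "sp",
                  environment = "e", X, emerged = 1L, measured = 1L,
                  survived = s)
  tab <- new("PhenotypeTable", data = d, traitNames = colnames(X))
  g <- selectionGradient(tab)
  e1 <- c(1, rep(0, p - 1))
  expect_gt(abs(sum(g@unit * e1)), 0.95)
  # the scaling chain is exact given the fitted model (oracle refit)
  fit <- glm(s ~ X, family = binomial())
  phat <- fit$fitted.values
  expect_equal(unname(g@logitScale), unname(coef(fit)[-1]), tolerance = 1e-10)
  expect_equal(g@probScale, g@logitScale * mean(phat * (1 - phat)))
  expect_equal(g@relScale, g@probScale / mean(s))
  expect_equal(sum(g@unit^2), 1)
  # Wald statistic for the true predictor dwarfs the null ones
  expect_gt(g@wald$chisq[1], max(g@wald$chisq[-1]) * 10)
})

test_that("balanced two-group survival gives the exact p = 0.5 scaling identities", {
  # group +1: 75% survive; group -1: 25% survive; counts exact, so the
  # fitted intercept is 0, mean survival is exactly 0.5, and the
  # evaluate-at-mean-fitness transform gives probability scale = 0.25 x
  # logit scale and relative scale = 0.5 x logit scale
  n4 <- 500
  x <- rep(c(1, 1, -1, -1), each = n4)
  s <- rep(c(1L, 0L, 1L, 0L), times = c(3 * n4 / 2, n4 / 2,
                                        n4 / 2, 3 * n4 / 2))
  x2 <- rep(c(1, -1), length.out = length(x))  # balanced, no effect
  d <- data.frame(individual_id = as.character(seq_along(x)), sire_id = "S1",
                  dam_id = "D1", block_id = "B1", species = "sp",
                  environment = "e", t1 = x, t2 = x2, emerged = 1L,
                  measured = 1L, survived = s)
  tab <- new("PhenotypeTable", data = d, traitNames = c("t1", "t2"))
  g <- selectionGradient(tab, derivativeAt = "meanFitness")
  expect_equal(g@meanSurvival, 0.5)
  expect_gt(abs(g@logitScale[["t1"]]), 1)      # genuinely nonzero gradient
  expect_equal(g@probScale, 0.25 * g@logitScale, tolerance = 1e-6)
  expect_equal(g@relScale, 0.5 * g@logitScale, tolerance = 1e-6)
})

test_that("selection gradient refuses inestimable contexts", {
  tab0 <- tinyTable()
  d <- as.data.frame(tab0); d$survived <- 1L
  allAlive <- new("PhenotypeTable", data = d, traitNames = c("t1", "t2"))
  expect_error(selectionGradient(allAlive), "single outcome")
  # too little post-measurement mortality
  d2 <- as.data.frame(tab0); d2$survived <- c(0L, rep(1L, 9))
  lowDeath <- new("PhenotypeTable", data = d2, traitNames = c("t1", "t2"))
  expect_error(selectionGradient(lowDeath, minDeathFraction = 0.2),
               "mortality")
  # complete separation is reported as such
  d3 <- as.data.frame(tab0); d3$survived <- as.integer(d3$t1 > 1.5)
  sep <- new("PhenotypeTable", data = d3, traitNames = c("t1", "t2"))
  expect_error(selectionGradient(sep), "separation")
})

test_that("genotypic gradient reduces to the individual gradient and is stable", {
  # families of size one: identical to the individual-level gradient
  set.seed(25)
  n <- 400
  X <- MASS::mvrnorm(n, rep(0, 3), diag(0.2, 3))
  colnames(X) <- paste0("t", 1:3)
  s <- rbinom(n, 1, plogis(X[, 1]))
  d <- data.frame(individual_id = as.character(1:n),
                  sire_id = paste0("S", 1:n), dam_id = paste0("D", 1:n),
                  block_id = "B1", species = "sp", environment = "e",
                  X, emerged = 1L, measured = 1L, survived = s)
  tab <- new("PhenotypeTable", data = d, traitNames = colnames(X))
  gi <- selectionGradient(tab)
  gf <- genotypicSelectionGradient(tab)
  expect_equal(gf@logitScale, gi@logitScale, tolerance = 1e-6)
  expect_equal(gf@unit, gi@unit, tolerance = 1e-6)

  # family structure: direction agrees with the individual-level gradient
  cfg <- quickConfig(nBlocks = 12L, damsPerBlock = 3L,
                     environments = "only", offspringPerFamilyPerEnv = 10L,
                     betaSurvival = list(intercept = 0, beta = c(1.5, 0, 0)),
                     seed = 33L)
  tab2 <- simulateDataset(cfg)
  gi2 <- selectionGradient(tab2)
  gf2 <- genotypicSelectionGradient(tab2)
  expect_gt(sum(gi2@unit * gf2@unit), 0.9)
  expect_error(genotypicSelectionGradient(tab2, minFamilies = 1000L),
               "families")
})

test_that("bootstrap gradients are reproducible and centered on the estimate", {
  set.seed(35)
  n <- 1500
  X <- MASS::mvrnorm(n, rep(0, 3), diag(0.3, 3))
  colnames(X) <- paste0("t", 1:3)
  s <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0)))
  d <- data.frame(individual_id = as.character(1:n), sire_id = "S1",
                  dam_id = "D1", block_id = "B1", species = "sp",
                  environment = "e", X, emerged = 1L, measured = 1L,
                  survived = as.integer(s))
  tab <- new("PhenotypeTable", data = d, traitNames = colnames(X))
  one <- bootstrapBeta(tab, nBoot = 1L, seed = 4L)
  expect_equal(nrow(one) + attr(one, "failures"), 1L)
  expect_identical(bootstrapBeta(tab, nBoot = 1L, seed = 4L), one)

  bb <- bootstrapBeta(tab, nBoot = 60L, seed = 9L)
  expect_equal(nrow(bb) + attr(bb, "failures"), 60L)
  g <- selectionGradient(tab)
  meanDir <- colMeans(bb); meanDir <- meanDir / sqrt(sum(meanDir^2))
  expect_gt(sum(meanDir * g@unit), 0.95)
  expect_error(bootstrapBeta(tab, nBoot = 0L), "nBoot")
})

test_that("D-matrix summarizes divergence among group means", {
  # all means equal: D = 0
  M <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  d0 <- computeD(M)
  expect_true(all(abs(d0@D) < 1e-12))

  # two groups: d_max parallel to the difference, single nonzero eigenvalue
  M2 <- rbind(g1 = c(1, 2, 3), g2 = c(2, 2, 1))
  colnames(M2) <- c("a", "b", "c")
  d2 <- computeD(M2)
  diff <- M2[1, ] - M2[2, ]
  expect_lt(angleBetween(d2@eigen@vectors[, 1], diff), 1e-8)
  expect_equal(sum(d2@eigen@values > 1e-12), 1L)

  # rank bound: 8 groups of 5 traits -> rank <= 7
  set.seed(45)
  M8 <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("t", 1:5)))
  expect_lte(sum(computeD(M8)@eigen@values > 1e-10), 7L)
  expect_error(computeD(M2[1, , drop = FALSE]), "2 groups")
})
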