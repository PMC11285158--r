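# eigenanalysis, angles, and the genetic covariance tensor

test_that("eigenanalysis returns sorted values, proportions, and signed vectors", {
  es <- eigenG(diag(c(3, 2, 1)))
  expect_equal(es@values, c(3, 2, 1))
  expect_equal(es@proportions, c(3, 2, 1) / 6)

  G <- matrix(c(1, 0.8, 0.8, 1), 2)
  es2 <- eigenG(G)
  expect_equal(es2@values, c(1.8, 0.2))
  expect_equal(unname(abs(es2@vectors[, 1])), rep(1 / sqrt(2), 2))
  expect_gt(es2@vectors[which.max(abs(es2@vectors[, 1])), 1], 0)

  # trace preserved
  set.seed(1)
  R <- randomPSD(5)
  expect_equal(sum(eigenG(R)@values), sum(diag(R)))

  A <- matrix(c(1, 2, 0, 1), 2)
  expect_error(eigenG(A), "asymmetric")
})

test_that("angles reproduce closed forms and a brute-force oracle", {
  v <- c(1, 2, 3)
  expect_lt(angleBetween(v, v), 1e-5)
  expect_lt(angleBetween(v, -v), 1e-5)          # sign-flip invariant
  expect_equal(angleBetween(c(1, 0), c(0, 1)), 90)
  # r = 0.5 -> 60 degrees
  expect_equal(angleBetween(c(1, 0), c(0.5, sqrt(3) / 2)), 60)
  expect_error(angleBetween(c(0, 0), v), "zero vector")

  set.seed(42)
  for (i in 1:1000) {
    p <- sample(2:6, 1)
    a <- rnorm(p); b <- rnorm(p)
    oracle <- acos(min(1, abs(sum(a * b) /
                                sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
    expect_lt(abs(angleBetween(a, b) - oracle), 1e-10)
  }
})

test_that("angle posteriors pair draws and respect range", {
  G <- randomPSD(3)
  a <- array(G, c(3, 3, 50))
  res <- anglePosterior(a, a)
  expect_equal(res$draws, rep(0, 50))

  b1 <- array(diag(c(2, 1)), c(2, 2, 30))
  b2 <- array(diag(c(1, 2)), c(2, 2, 30))
  res2 <- anglePosterior(b1, b2)
  expect_equal(res2$draws, rep(90, 30))

  set.seed(3)
  c1 <- array(unlist(replicate(40, randomPSD(3), simplify = FALSE)),
              c(3, 3, 40))
  c2 <- array(unlist(replicate(25, randomPSD(3), simplify = FALSE)),
              c(3, 3, 25))
  expect_warning(res3 <- anglePosterior(c1, c2), "draw counts differ")
  expect_length(res3$draws, 25)
  expect_true(all(res3$draws >= 0 & res3$draws <= 90))
})

test_that("vectorization is the Frobenius isometry", {
  expect_equal(vectorizeG(diag(c(1, 1))), c(1, 0, 1))
  G <- matrix(c(1, 0.5, 0.5, 2), 2)
  expect_equal(vectorizeG(G), c(1, 0.5 * sqrt(2), 2))
  set.seed(2)
  for (i in 1:20) {
    p <- sample(2:6, 1)
    A <- randomPSD(p); B <- randomPSD(p)
    expect_equal(sum(vectorizeG(A)^2), sum(A^2))              # isometry
    expect_equal(sum(vectorizeG(A) * vectorizeG(B)), sum(A * B))
    expect_equal(unvectorizeG(vectorizeG(A)), A)              # inverse
  }
})

test_that("tensor matches an independent brute-force construction", {
  # hand-built example: G1 = diag(1,1), G2 = diag(2,1)
  G1 <- diag(c(1, 1)); G2 <- diag(c(2, 1))
  tens <- covarianceTensor(list(G1, G2))

  # brute-force oracle built from first principles: stack unique elements
  # with sqrt(2) off-diagonal weights, covariance across matrices, eigen
  stack <- function(G) c(G[1, 1], sqrt(2) * G[2, 1], G[2, 2])
  V <- rbind(stack(G1), stack(G2))
  Soracle <- matrix(0, 3, 3)
  for (i in 1:2) {
    dev <- V[i, ] - colMeans(V)
    Soracle <- Soracle + tcrossprod(dev)
  }
  Soracle <- Soracle / (2 - 1)
  expect_equal(tens@S, Soracle)
  eo <- eigen(Soracle)
  expect_equal(tens@values, eo$values)

  expect_equal(tens@values[1], 0.5)
  expect_equal(tens@values[-1], c(0, 0))
  expect_equal(tens@tensors$E1, diag(c(1, 0)))
  expect_equal(unname(tens@coordinates[, 1]), c(1, 2))
})

test_that("m generic matrices give exactly m - 1 nonzero eigentensors", {
  set.seed(7)
  Gs <- replicate(8, randomPSD(5), simplify = FALSE)
  tens <- covarianceTensor(Gs)
  expect_equal(sum(tens@values > 1e-10), 7L)
  # identical matrices give a zero tensor
  same <- covarianceTensor(replicate(4, Gs[[1]], simplify = FALSE))
  expect_true(all(abs(same@values) < 1e-12))
  expect_error(covarianceTensor(Gs[1]), "at least 2")
})

test_that("tensor reconstruction, orthonormality and the coordinate-variance identity hold", {
  set.seed(11)
  for (rep in 1:25) {
    m <- sample(3:8, 1); p <- sample(2:5, 1)
    Gs <- replicate(m, randomPSD(p), simplify = FALSE)
    tens <- covarianceTensor(Gs)
    k <- length(tens@values)
    # S = sum_k lambda_k vec(E_k) vec(E_k)'
    Srec <- Reduce(`+`, lapply(seq_len(k), function(j)
      tens@values[j] * tcrossprod(vectorizeG(tens@tensors[[j]]))))
    expect_lt(max(abs(Srec - tens@S)), 1e-10)
    # Frobenius orthonormality
    for (a in seq_len(k)) for (b in seq_len(a)) {
      fr <- sum(tens@tensors[[a]] * tens@tensors[[b]])
      expect_lt(abs(fr - as.numeric(a == b)), 1e-10)
    }
    # variance of coordinates across matrices equals the eigenvalue
    for (j in seq_len(k))
      expect_lt(abs(var(tens@coordinates[, j]) - tens@values[j]), 1e-8)
  }
})

test_that("a single perturbed matrix isolates the perturbation direction", {
  set.seed(13)
  G <- randomPSD(4)
  P <- matrix(0, 4, 4); P[1, 2] <- P[2, 1] <- 0.3; P[1, 1] <- 0.5
  Gs <- c(replicate(5, G, simplify = FALSE), list(G + P))
  tens <- covarianceTensor(Gs)
  corr <- sum(vectorizeG(tens@tensors$E1) * vectorizeG(P)) /
    sqrt(sum(vectorizeG(P)^2))
  expect_gt(abs(corr), 0.99)
})

test_that("matrix coordinates are Frobenius inner products, linear in G", {
  expect_equal(matrixCoordinates(diag(c(1, 1)), diag(c(1, 0))), 1)
  set.seed(5)
  A <- randomPSD(3); B <- randomPSD(3); E <- randomPSD(3)
  expect_equal(matrixCoordinates(2 * A + 3 * B, E),
               2 * matrixCoordinates(A, E) + 3 * matrixCoordinates(B, E))
  expect_error(matrixCoordinates(A, randomPSD(4)), "dimension")
})

test_that("tensor of posterior draws gives per-draw coordinates", {
  set.seed(9)
  n <- 30
  arr1 <- array(0, c(2, 2, n)); arr2 <- array(0, c(2, 2, n))
  for (i in seq_len(n)) {
    arr1[, , i] <- diag(c(1, 1)) + randomPSD(2) * 0.01
    arr2[, , i] <- diag(c(2, 1)) + randomPSD(2) * 0.01
  }
  tens <- covarianceTensor(list(A = arr1, B = arr2))
  expect_equal(dim(tens@coordinateDraws), c(2L, 3L, n))
  expect_equal(tens@coordinates["A", "E1"],
               mean(tens@coordinateDraws["A", "E1", ]))
  # leading structure matches the underlying point tensor
  expect_lt(abs(tens@values[1] - 0.5), 0.05)
})
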