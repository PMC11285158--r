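#' @include AllGenerics.R
NULL

#' Eigenanalysis of a covariance matrix
#'
#' Decomposes G into independent axes of genetic variation: eigenvalues in
#' decreasing order, unit eigenvectors with a deterministic sign convention
#' (the largest-magnitude loading of each vector is made positive), and
#' variance proportions. The leading eigenvector is g_max, the trait
#' combination with the most genetic variance.
#'
#' @param G symmetric matrix (asymmetry beyond `tol` is an error).
#' @param traitNames optional trait names.
#' @param tol relative symmetry tolerance.
#' @return an [EigenSummary-class].
#' @export
eigenG <- function(G, traitNames = NULL, tol = 1e-8) {
  if (!is.matrix(G) || nrow(G) != ncol(G)) stop("G must be square")
  if (max(abs(G - t(G))) > tol * max(1, max(abs(G))))
    stop("G is asymmetric beyond tolerance")
  if (is.null(traitNames)) {
    traitNames <- rownames(G)
    if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(nrow(G)))
  }
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- traitNames
  tot <- sum(e$values)
  prop <- if (tot > 0) e$values / tot else rep(0, length(e$values))
  new("EigenSummary", values = e$values, vectors = V, proportions = prop,
      traitNames = traitNames)
}

#' Angle between two directions in trait space
#'
#' theta = arccos(|r|) * 180 / pi where r is the vector correlation (inner
#' product of the normalized vectors). The absolute value makes the angle
#' invariant to sign flips of either vector, so theta lies in [0, 90]
#' degrees.
#'
#' @param v1,v2 nonzero vectors (normalized internally).
#' @return angle in degrees.
#' @export
angleBetween <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  r <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, abs(r))) * 180 / pi
}

#' Posterior distribution of the angle between eigenvectors of two G's
#'
#' Pairs draws by index from the two posteriors (chains are independent, so
#' index pairing is arbitrary but harmless), computes the chosen eigenvector
#' of each draw, and returns the posterior of the angle between them.
#'
#' @param gpostA,gpostB [GPosterior-class] objects or p x p x n arrays of G
#'   draws.
#' @param axis which eigenvector to compare (1 = g_max).
#' @return list: `draws` (degrees), `mean`, `hpd` (95%).
#' @export
anglePosterior <- function(gpostA, gpostB, axis = 1L) {
  a <- if (is(gpostA, "GPosterior")) extractG(gpostA) else gpostA
  b <- if (is(gpostB, "GPosterior")) extractG(gpostB) else gpostB
  if (dim(a)[1] != dim(b)[1]) stop("trait dimensions differ")
  n <- min(dim(a)[3], dim(b)[3])
  if (dim(a)[3] != dim(b)[3])
    warning("draw counts differ; pairing the first ", n, " draws")
  th <- vapply(seq_len(n), function(i) {
    va <- eigenG(a[, , i])@vectors[, axis]
    vb <- eigenG(b[, , i])@vectors[, axis]
    angleBetween(va, vb)
  }, 0)
  list(draws = th, mean = mean(th), hpd = hpdInterval(th))
}

#' Vectorize a symmetric matrix for the covariance tensor
#'
#' Stacks the p(p+1)/2 unique elements (lower triangle, column-major) with
#' off-diagonal elements weighted by sqrt(2), so the Euclidean inner product
#' of two vectorized matrices equals the Frobenius inner product of the
#' matrices (an isometry).
#'
#' @param G symmetric p x p matrix.
#' @return numeric vector of length p(p+1)/2.
#' @export
vectorizeG <- function(G) {
  p <- nrow(G)
  w <- matrix(sqrt(2), p, p); diag(w) <- 1
  (G * w)[lower.tri(G, diag = TRUE)]
}

#' Rebuild a symmetric matrix from its tensor vectorization
#'
#' Inverse of [vectorizeG()]: undoes the sqrt(2) off-diagonal weighting. A
#' unit-norm input vector yields a matrix with unit Frobenius norm.
#'
#' @param v vector of length p(p+1)/2.
#' @return symmetric p x p matrix.
#' @export
unvectorizeG <- function(v) {
  p <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(p - round(p)) > 1e-8) stop("length is not p(p+1)/2")
  p <- as.integer(round(p))
  M <- matrix(0, p, p)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M) - diag(diag(M))
  w <- matrix(1 / sqrt(2), p, p); diag(w) <- 1
  M * w
}

# S-matrix (covariance of vectorized G's, denominator m - 1) of a list of
# matrices, and the matrix of vectorizations.
buildS <- function(Gs) {
  V <- t(vapply(Gs, vectorizeG, numeric(length(vectorizeG(Gs[[1]])))))
  list(S = cov(V), V = V)
}

#' Genetic covariance tensor of a set of G-matrices
#'
#' Builds the S-matrix — the covariance matrix (denominator m - 1) of the
#' vectorized unique elements of the m input G-matrices — and eigenanalyzes
#' it. Eigenvectors of S, rearranged back into symmetric matrices, are the
#' eigentensors: orthonormal (Frobenius) axes of variation among the
#' G-matrices. The coordinate of G_i on eigentensor E_k is the Frobenius
#' inner product; matrices with larger coordinates contribute more to the
#' differences described by that eigentensor, and across the m matrices the
#' coordinates on E_k have variance exactly equal to the k-th eigenvalue
#' of S.
#'
#' When posterior draw arrays are supplied, S is computed for every paired
#' posterior draw (draw i of each context) and averaged; eigentensors come
#' from the posterior-mean S, and coordinates are computed per draw so their
#' posterior distributions are returned alongside the means.
#'
#' @param Gs list of m symmetric p x p matrices, or a list of
#'   [GPosterior-class] / p x p x n arrays.
#' @param labels optional labels for the m matrices.
#' @return a [TensorResult-class]. Eigentensor sign convention: the
#'   largest-magnitude element of each eigentensor is positive.
#' @export
covarianceTensor <- function(Gs, labels = NULL) {
  if (length(Gs) < 2) stop("need at least 2 matrices")
  if (is.null(labels)) {
    labels <- names(Gs)
    if (is.null(labels)) labels <- paste0("G", seq_along(Gs))
  }
  posterior <- !all(vapply(Gs, is.matrix, TRUE))
  if (posterior) {
    arrs <- lapply(Gs, function(g)
      if (is(g, "GPosterior")) extractG(g) else g)
    p <- dim(arrs[[1]])[1]
    for (a in arrs) if (dim(a)[1] != p) stop("trait dimensions differ")
    n <- min(vapply(arrs, function(a) dim(a)[3], 0))
    q <- p * (p + 1) / 2
    Smean <- matrix(0, q, q)
    for (i in seq_len(n)) {
      Smean <- Smean + buildS(lapply(arrs, function(a) a[, , i]))$S
    }
    S <- Smean / n
  } else {
    p <- nrow(Gs[[1]])
    for (g in Gs) if (nrow(g) != p) stop("matrix dimensions differ")
    S <- buildS(Gs)$S
  }

  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  k <- length(e$values)
  tensors <- vector("list", k)
  for (j in seq_len(k)) {
    v <- e$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    tensors[[j]] <- unvectorizeG(v)
  }
  names(tensors) <- paste0("E", seq_len(k))

  if (posterior) {
    m <- length(arrs)
    coordDraws <- array(NA_real_, c(m, k, n),
                        dimnames = list(labels, names(tensors), NULL))
    for (i in seq_len(n)) for (g in seq_len(m)) {
      Gi <- arrs[[g]][, , i]
      coordDraws[g, , i] <- vapply(tensors, function(E) sum(Gi * E), 0)
    }
    coords <- apply(coordDraws, c(1, 2), mean)
  } else {
    m <- length(Gs)
    coords <- matrix(NA_real_, m, k, dimnames = list(labels, names(tensors)))
    for (g in seq_len(m))
      coords[g, ] <- vapply(tensors, function(E) sum(Gs[[g]] * E), 0)
    coordDraws <- array(numeric(0), c(0, 0, 0))
  }

  new("TensorResult", S = S, values = e$values, tensors = tensors,
      coordinates = coords, coordinateDraws = coordDraws,
      matrixLabels = labels,
      nullValues = matrix(numeric(0), 0, k),
      significant = rep(NA, k))
}

#' Coordinate of a matrix on an eigentensor
#'
#' Frobenius inner product sum_ij G_ij E_ij; linear in G.
#'
#' @param G symmetric matrix.
#' @param eigentensor symmetric matrix of the same dimension.
#' @return scalar coordinate.
#' @export
matrixCoordinates <- function(G, eigentensor) {
  if (!all(dim(G) == dim(eigentensor))) stop("dimension mismatch")
  sum(G * eigentensor)
}

#' Null distribution for eigentensor eigenvalues by breeding-value
#' randomization
#'
#' Simulates changes in G due only to random sampling: for each null
#' replicate and each context, the predicted (posterior-mean) sire effects
#' are permuted among sires, phenotypes are reconstructed as the permuted
#' sire effect plus the retained dam/block/residual remainder, the model is
#' refit, and the covariance tensor of the null G's is recomputed. An
#' observed eigentensor is significant when its eigenvalue exceeds the
#' (1 - alpha) quantile of the null eigenvalues of the same rank.
#'
#' @param fits list of [GPosterior-class] objects, one per context.
#' @param observed optional pre-computed observed [TensorResult-class]
#'   (default: tensor of `fits`).
#' @param nSim number of null replicates (< 20 warns).
#' @param mcmc reduced [MCMCSettings-class] for null refits.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return the observed [TensorResult-class] with `nullValues` and
#'   `significant` filled in.
#' @export
nullTensor <- function(fits, observed = NULL, nSim = 100L,
                       mcmc = mcmcSettings(nBurnin = 500, thin = 2,
                                           nSamples = 250),
                       alpha = 0.05, seed = 1L) {
  if (nSim < 1) stop("nSim must be positive")
  if (nSim < 20) warning("nSim < 20: null quantiles are unstable")
  if (is.null(observed))
    observed <- covarianceTensor(fits,
                                 labels = vapply(fits, contextLabel, ""))
  k <- length(observed@values)
  nullVals <- matrix(NA_real_, nSim, k)
  for (r in seq_len(nSim)) {
    nullGs <- vector("list", length(fits))
    for (f in seq_along(fits)) {
      fit <- fits[[f]]
      md <- fit@modelData
      sEff <- fit@effects$sire
      set.seed(deriveSeed(seed, sprintf("bvperm-%d-%d", r, f)))
      perm <- sample(nrow(sEff))
      # replace each row's sire contribution by a permuted sire's effect
      Ynull <- md$Y - sEff[md$sire + 1L, , drop = FALSE] +
        sEff[perm[md$sire + 1L], , drop = FALSE]
      d <- data.frame(
        individual_id = as.character(seq_len(nrow(Ynull))),
        sire_id = md$sireLevels[md$sire + 1L],
        dam_id = sub("^.*\r", "", md$damLevels[md$dam + 1L]),
        block_id = md$blockLevels[md$block + 1L],
        species = fit@species, environment = fit@environment,
        stringsAsFactors = FALSE)
      colnames(Ynull) <- fit@traitNames
      d <- cbind(d, as.data.frame(Ynull))
      d$emerged <- 1L; d$measured <- 1L; d$survived <- NA_integer_
      tabNull <- new("PhenotypeTable", data = d,
                     traitNames = fit@traitNames)
      nf <- fitHalfsib(tabNull,
                       mcmc = new("MCMCSettings", nBurnin = mcmc@nBurnin,
                                  thin = mcmc@thin, nSamples = mcmc@nSamples,
                                  seed = deriveSeed(seed,
                                                    sprintf("bvfit-%d-%d",
                                                            r, f))))
      nullGs[[f]] <- nf
    }
    # null tensor computed the same way as the observed one (per paired
    # posterior draw), so observed and null eigenvalues carry comparable
    # posterior sampling noise
    nullVals[r, ] <- covarianceTensor(nullGs)@values
  }
  sig <- vapply(seq_len(k), function(j)
    observed@values[j] > quantile(nullVals[, j], 1 - alpha), TRUE)
  observed@nullValues <- nullVals
  observed@significant <- sig
  observed
}
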