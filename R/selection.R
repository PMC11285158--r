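#' @include AllGenerics.R
NULL

newDirection <- function(v, kind, labels = character()) {
  new("DirectionVector", vector = as.numeric(v), kind = kind,
      labels = labels, degenerate = sqrt(sum(v^2)) < 1e-12)
}

#' Plasticity vector between two environments
#'
#' Difference in mean multivariate phenotype, native environment minus the
#' other environment (for mean-standardized traits). A zero difference is
#' flagged degenerate: it has no direction and cannot be projected.
#'
#' @param meansNative,meansOther named trait-mean vectors (same traits).
#' @param labels optional named character labels (species, from, to).
#' @return a [DirectionVector-class] of kind "plasticity".
#' @export
plasticityVector <- function(meansNative, meansOther, labels = character()) {
  if (length(meansNative) != length(meansOther))
    stop("trait dimensions differ")
  newDirection(meansNative - meansOther, "plasticity", labels)
}

#' Native-phenotype direction between species at one environment
#'
#' Species-difference vector: the mean phenotype of the native species minus
#' that of the other species at the same environment, pointing toward the
#' native phenotype.
#'
#' @param meansNativeSpecies,meansOtherSpecies named trait-mean vectors.
#' @param environment label of the shared environment.
#' @param labels extra labels.
#' @return a [DirectionVector-class] of kind "native-difference".
#' @export
nativeDirection <- function(meansNativeSpecies, meansOtherSpecies,
                            environment = NA_character_,
                            labels = character()) {
  if (length(meansNativeSpecies) != length(meansOtherSpecies))
    stop("trait dimensions differ")
  newDirection(meansNativeSpecies - meansOtherSpecies, "native-difference",
               c(labels, environment = environment))
}

#' Proportion of genetic variance in a direction
#'
#' The projection (v' G v) / lambda_max: genetic variance in the direction v
#' as a proportion of the maximum genetic variance available (lambda_max is
#' the leading eigenvalue of the same G). v is normalized to unit length
#' internally — without normalization the ratio is not bounded by 1 and the
#' proportion interpretation fails. Always in [0, 1]; equals lambda_k /
#' lambda_max when v is the k-th eigenvector, and 1 when v = g_max.
#'
#' @param v a [DirectionVector-class] or numeric vector.
#' @param G symmetric PSD matrix.
#' @param lambdaMax leading eigenvalue of G (computed if NULL).
#' @return scalar proportion in [0, 1].
#' @export
projectThroughG <- function(v, G, lambdaMax = NULL) {
  if (is(v, "DirectionVector")) v <- unitVector(v)
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector has no direction")
  v <- v / n
  if (is.null(lambdaMax))
    lambdaMax <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (lambdaMax <= 0) stop("lambda_max must be positive")
  as.numeric(t(v) %*% G %*% v) / lambdaMax
}

#' Posterior/bootstrap distribution of a projection through G
#'
#' Computes the proportion of genetic variance in the direction of each
#' vector draw for posterior draws of G. With `pairing = "sample"` (default)
#' each vector draw is paired with one randomly chosen G draw, keeping the
#' draw count at max(nVec, nG); `pairing = "cross"` evaluates the full
#' nVec x nG cross, capped at `maxDraws`.
#'
#' @param vDraws a single vector/[DirectionVector-class], or a matrix with
#'   one vector draw per row (e.g. bootstrap draws of a selection gradient).
#' @param gDraws a [GPosterior-class] or p x p x n array of G draws.
#' @param pairing "sample" or "cross".
#' @param maxDraws cap on the number of returned draws.
#' @param label description of the projection.
#' @param seed RNG seed for the pairing.
#' @return a [ProjectionResult-class].
#' @export
projectPosterior <- function(vDraws, gDraws, pairing = c("sample", "cross"),
                             maxDraws = 100000L, label = "projection",
                             seed = 1L) {
  pairing <- match.arg(pairing)
  if (is(vDraws, "DirectionVector")) vDraws <- unitVector(vDraws)
  if (is.null(dim(vDraws))) vDraws <- matrix(vDraws, nrow = 1)
  G <- if (is(gDraws, "GPosterior")) extractG(gDraws) else gDraws
  if (length(dim(G)) == 2) G <- array(G, c(dim(G), 1))
  nv <- nrow(vDraws); ng <- dim(G)[3]
  if (nv < 1 || ng < 1) stop("empty vector or G draws")
  lmax <- vapply(seq_len(ng), function(i)
    max(eigen(G[, , i], symmetric = TRUE, only.values = TRUE)$values), 0)
  if (pairing == "cross") {
    idx <- expand.grid(v = seq_len(nv), g = seq_len(ng))
    if (nrow(idx) > maxDraws) {
      set.seed(deriveSeed(seed, "projection-cross"))
      idx <- idx[sample(nrow(idx), maxDraws), ]
    }
  } else {
    n <- min(max(nv, ng), maxDraws)
    set.seed(deriveSeed(seed, "projection-pairing"))
    idx <- data.frame(
      v = if (nv == n) seq_len(n) else sample(nv, n, replace = TRUE),
      g = if (ng == n) seq_len(n) else sample(ng, n, replace = TRUE))
  }
  pr <- vapply(seq_len(nrow(idx)), function(k) {
    projectThroughG(vDraws[idx$v[k], ], G[, , idx$g[k]],
                    lambdaMax = lmax[idx$g[k]])
  }, 0)
  new("ProjectionResult", draws = pmin(1, pmax(0, pr)), label = label)
}

#' Overlap of two projection distributions at an HPD level
#'
#' Reports whether the HPD intervals of two projection distributions overlap
#' at the given level; non-overlap at a high level indicates a credible
#' difference in available genetic variance between contexts.
#'
#' @param a,b [ProjectionResult-class] objects.
#' @param level HPD probability (default 0.9).
#' @return list: `overlap` (logical), `hpdA`, `hpdB`.
#' @export
hpdOverlap <- function(a, b, level = 0.9) {
  ha <- hpdInterval(draws(a), level)
  hb <- hpdInterval(draws(b), level)
  list(overlap = ha[1] <= hb[2] && hb[1] <= ha[2], hpdA = ha, hpdB = hb)
}

# shared scaling chain: logit coefficients -> probability scale (average
# derivative mean(phat (1 - phat)), or p(1-p) evaluated at mean survival) ->
# relative-fitness scale (divide by mean survival) -> unit direction
scaleGradient <- function(fit, tn, meanSurv, n, labels,
                          derivativeAt = c("average", "meanFitness")) {
  derivativeAt <- match.arg(derivativeAt)
  cf <- coef(fit)[tn]
  phat <- fit$fitted.values
  deriv <- if (derivativeAt == "average") mean(phat * (1 - phat))
           else meanSurv * (1 - meanSurv)
  probScale <- cf * deriv
  relScale <- probScale / meanSurv
  se <- sqrt(diag(vcov(fit)))[tn]
  wald <- data.frame(trait = tn, chisq = (cf / se)^2,
                     p = pchisq((cf / se)^2, df = 1, lower.tail = FALSE),
                     row.names = NULL)
  new("SelectionGradientResult", logitScale = cf, probScale = probScale,
      relScale = relScale, unit = relScale / sqrt(sum(relScale^2)),
      meanSurvival = meanSurv, wald = wald, n = as.integer(n),
      labels = labels)
}

#' Viability selection gradient from binary survival
#'
#' Multiple logistic regression of survival on all traits jointly; the
#' multivariate fit supplies the phenotypic-covariance adjustment of
#' beta = P^-1 s. Coefficients are returned on the logit scale, the
#' probability scale (average-gradient transform: logit coefficients times
#' the mean of fitted p(1-p)), and the relative-fitness scale (probability
#' scale divided by mean survival); the unit-length relative-scale vector is
#' the estimated direction of selection. Per-trait Wald chi-square statistics
#' are included.
#'
#' Selection is only estimable where mortality occurred after measurement:
#' contexts where fewer than `minDeathFraction` of measured individuals died
#' are refused.
#'
#' @param table a [PhenotypeTable-class] (ideally mean-standardized).
#' @param species,environment optional context filters.
#' @param derivativeAt "average" (mean of fitted p(1-p); default) or
#'   "meanFitness" (evaluate p(1-p) at mean survival).
#' @param minDeathFraction minimum fraction of post-measurement deaths
#'   (default 0.05); set to 0 to disable the check.
#' @return a [SelectionGradientResult-class].
#' @export
selectionGradient <- function(table, species = NULL, environment = NULL,
                              derivativeAt = c("average", "meanFitness"),
                              minDeathFraction = 0.05) {
  tab <- subsetContext(table, species, environment, measuredOnly = TRUE)
  d <- as.data.frame(tab)
  tn <- traitNames(tab)
  if (!nrow(d)) stop("no measured individuals")
  s <- d$survived
  if (all(s == 1) || all(s == 0))
    stop("survival has a single outcome; selection is inestimable")
  if (mean(s == 0) < minDeathFraction)
    stop(sprintf(paste0("only %.1f%% of measured individuals died; ",
                        "selection is estimable only where substantial ",
                        "mortality occurred after measurement"),
                 100 * mean(s == 0)))
  X <- as.data.frame(d[, tn, drop = FALSE])
  fit <- withCallingHandlers(
    glm(s ~ ., data = cbind(s = s, X), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("complete separation: survival is perfectly predicted; ",
             "reduce traits or pool contexts", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  scaleGradient(fit, tn, mean(s), nrow(d),
                c(species = as.character(d$species[1]),
                  environment = as.character(d$environment[1])),
                derivativeAt)
}

#' Genotypic selection gradient from family means
#'
#' The same computation on family means: traits averaged per full-sib family
#' and survival as the family survival fraction, fit by quasi-binomial
#' logistic regression weighted by family size, followed by the same scaling
#' chain. Families of size one reduce exactly to the individual-level
#' gradient.
#'
#' @inheritParams selectionGradient
#' @param minFamilies minimum number of families (default 10).
#' @return a [SelectionGradientResult-class].
#' @export
genotypicSelectionGradient <- function(table, species = NULL,
                                       environment = NULL,
                                       derivativeAt = c("average",
                                                        "meanFitness"),
                                       minDeathFraction = 0.05,
                                       minFamilies = 10L) {
  tab <- subsetContext(table, species, environment, measuredOnly = TRUE)
  d <- as.data.frame(tab)
  tn <- traitNames(tab)
  fam <- paste(d$sire_id, d$dam_id, sep = "x")
  if (length(unique(fam)) < minFamilies)
    stop("fewer than ", minFamilies, " families with measured offspring")
  agg <- aggregate(d[, c(tn, "survived")], by = list(.fam = fam), FUN = mean)
  famSizes <- vapply(split(fam, fam), length, 0L)
  w <- as.numeric(famSizes[agg$.fam])
  s <- agg$survived
  if (all(s == 1) || all(s == 0))
    stop("survival has a single outcome; selection is inestimable")
  if (sum(w * (1 - s)) / sum(w) < minDeathFraction)
    stop("insufficient post-measurement mortality for selection estimation")
  X <- agg[, tn, drop = FALSE]
  fit <- suppressWarnings(
    glm(s ~ ., data = cbind(s = s, X), family = quasibinomial(), weights = w))
  scaleGradient(fit, tn, sum(w * s) / sum(w), nrow(agg),
                c(species = as.character(d$species[1]),
                  environment = as.character(d$environment[1])),
                derivativeAt)
}

#' Bootstrap draws of the selection gradient
#'
#' Case-resampling bootstrap: measured individuals of the context are
#' resampled with replacement and the gradient recomputed per replicate.
#' Replicates that fail to refit (e.g. complete separation) are dropped and
#' counted in the `failures` attribute.
#'
#' @inheritParams selectionGradient
#' @param nBoot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param scale which coefficient scale to collect ("unit", "relative",
#'   "prob", "logit").
#' @return matrix with one bootstrap draw per row (`failures` attribute
#'   counts dropped replicates).
#' @export
bootstrapBeta <- function(table, nBoot = 1000L, seed = 1L,
                          species = NULL, environment = NULL,
                          scale = c("unit", "relative", "prob", "logit"),
                          minDeathFraction = 0.05) {
  if (nBoot < 1) stop("nBoot must be >= 1")
  scale <- match.arg(scale)
  tab <- subsetContext(table, species, environment, measuredOnly = TRUE)
  d <- as.data.frame(tab)
  tn <- traitNames(tab)
  set.seed(deriveSeed(seed, "bootstrap-beta"))
  out <- matrix(NA_real_, nBoot, length(tn), dimnames = list(NULL, tn))
  fail <- 0L
  for (b in seq_len(nBoot)) {
    idx <- sample(nrow(d), replace = TRUE)
    db <- d[idx, , drop = FALSE]
    db$individual_id <- as.character(seq_len(nrow(db)))  # resampled copies
    bt <- new("PhenotypeTable", data = db, traitNames = tn)
    g <- tryCatch(selectionGradient(bt,
                                    minDeathFraction = minDeathFraction),
                  error = function(e) NULL)
    if (is.null(g)) { fail <- fail + 1L; next }
    out[b, ] <- switch(scale, unit = g@unit, relative = g@relScale,
                       prob = g@probScale, logit = g@logitScale)
  }
  out <- out[!is.na(out[, 1]), , drop = FALSE]
  attr(out, "failures") <- fail
  out
}

#' D-matrix of divergence among group mean phenotypes
#'
#' Covariance matrix (denominator n_groups - 1) of the group trait-mean
#' vectors; its leading axes d_max and d_2 are the main directions of
#' mean-phenotype change, and group scores are the centered means projected
#' on those axes. Rank is at most n_groups - 1.
#'
#' @param means matrix of group means (one group per row), or the data.frame
#'   from [groupMeans()] together with `traitNames`.
#' @param traitNames trait columns when `means` is a data.frame.
#' @return a [DMatrixResult-class].
#' @export
computeD <- function(means, traitNames = NULL) {
  if (is.data.frame(means)) {
    if (is.null(traitNames)) stop("traitNames required for data.frame input")
    labs <- apply(means[, setdiff(names(means), traitNames), drop = FALSE],
                  1, paste, collapse = " @ ")
    means <- as.matrix(means[, traitNames, drop = FALSE])
    rownames(means) <- labs
  }
  if (nrow(means) < 2) stop("need at least 2 groups")
  labs <- rownames(means)
  if (is.null(labs)) labs <- paste0("group", seq_len(nrow(means)))
  D <- cov(means)
  es <- eigenG(D, traitNames = colnames(means))
  ctr <- sweep(means, 2, colMeans(means))
  scores <- ctr %*% es@vectors
  rownames(scores) <- labs
  new("DMatrixResult", D = D, eigen = es, scores = scores,
      groupLabels = labs)
}
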