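#' @include AllClasses.R
NULL

#' Trait names of an object
#' @param x an object carrying trait names.
#' @return character vector of trait names.
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname traitNames
#' @export
setMethod("traitNames", "PhenotypeTable", function(x) x@traitNames)
#' @rdname traitNames
#' @export
setMethod("traitNames", "GPosterior", function(x) x@traitNames)
#' @rdname traitNames
#' @export
setMethod("traitNames", "SimConfig", function(x) x@traitNames)

#' Number of posterior draws
#' @param x a GPosterior or ProjectionResult.
#' @return integer draw count.
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname nDraws
#' @export
setMethod("nDraws", "GPosterior", function(x) dim(x@sigmaSire)[3])
#' @rdname nDraws
#' @export
setMethod("nDraws", "ProjectionResult", function(x) length(x@draws))

#' Extract raw draws
#' @param x an object holding draws.
#' @param ... passed to methods.
#' @return numeric vector (scalar posteriors) or array (matrix posteriors).
#' @export
setGeneric("draws", function(x, ...) standardGeneric("draws"))

#' @rdname draws
#' @export
setMethod("draws", "ProjectionResult", function(x, ...) x@draws)

#' Posterior mean of a variance component
#' @param x a GPosterior.
#' @param component one of "sire", "dam", "block", "resid".
#' @return p x p posterior-mean covariance matrix.
#' @export
setGeneric("posteriorMean", function(x, component = "sire")
  standardGeneric("posteriorMean"))

#' @rdname posteriorMean
#' @export
setMethod("posteriorMean", "GPosterior", function(x, component = "sire") {
  a <- switch(match.arg(component, c("sire", "dam", "block", "resid")),
              sire = x@sigmaSire, dam = x@sigmaDam,
              block = x@sigmaBlock, resid = x@sigmaResid)
  m <- apply(a, c(1, 2), mean)
  dimnames(m) <- list(x@traitNames, x@traitNames)
  m
})

#' Context label of a fitted posterior
#' @param x a GPosterior.
#' @return character "species @ environment".
#' @export
setGeneric("contextLabel", function(x) standardGeneric("contextLabel"))

#' @rdname contextLabel
#' @export
setMethod("contextLabel", "GPosterior",
          function(x) paste(x@species, x@environment, sep = " @ "))

#' The raw direction vector
#' @param x a DirectionVector.
#' @return numeric p-vector.
#' @export
setGeneric("rawVector", function(x) standardGeneric("rawVector"))

#' @rdname rawVector
#' @export
setMethod("rawVector", "DirectionVector", function(x) x@vector)

#' Unit-length direction
#' @param x a DirectionVector.
#' @return numeric p-vector with norm 1.
#' @export
setGeneric("unitVector", function(x) standardGeneric("unitVector"))

#' @rdname unitVector
#' @export
setMethod("unitVector", "DirectionVector", function(x) {
  if (x@degenerate) stop("degenerate (zero) direction cannot be normalized")
  x@vector / sqrt(sum(x@vector^2))
})

#' Convert to data.frame
#' @param x a PhenotypeTable.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "PhenotypeTable", function(x, ...) x@data)

#' @describeIn PhenotypeTable number of rows and trait count.
#' @param object a PhenotypeTable.
#' @export
setMethod("show", "PhenotypeTable", function(object) {
  d <- object@data
  cat(sprintf("PhenotypeTable: %d individuals, %d traits\n",
              nrow(d), length(object@traitNames)))
  cat("  traits:", paste(object@traitNames, collapse = ", "), "\n")
  cat(sprintf("  species: %s | environments: %s\n",
              paste(unique(d$species), collapse = ", "),
              paste(unique(d$environment), collapse = ", ")))
  cat(sprintf("  measured: %d | survived (of measured): %d\n",
              sum(d$measured == 1),
              sum(d$survived == 1 & d$measured == 1, na.rm = TRUE)))
})

#' @describeIn GPosterior brief summary of the posterior.
#' @param object a GPosterior.
#' @export
setMethod("show", "GPosterior", function(object) {
  cat(sprintf("GPosterior [%s]: %d draws, %d traits\n",
              contextLabel(object), nDraws(object),
              length(object@traitNames)))
  cat("posterior mean sire (co)variance matrix (G):\n")
  print(round(posteriorMean(object, "sire"), 4))
})

#' @describeIn EigenSummary eigenvalues and variance proportions.
#' @param object an EigenSummary.
#' @export
setMethod("show", "EigenSummary", function(object) {
  cat("EigenSummary\n")
  print(data.frame(eigenvalue = round(object@values, 5),
                   proportion = round(object@proportions, 4)))
})

#' @describeIn TensorResult eigenvalues and significance flags.
#' @param object a TensorResult.
#' @export
setMethod("show", "TensorResult", function(object) {
  cat(sprintf("Genetic covariance tensor of %d matrices\n",
              nrow(object@coordinates)))
  tot <- sum(object@values)
  print(data.frame(
    eigentensor = paste0("E", seq_along(object@values)),
    eigenvalue = round(object@values, 6),
    pct = if (tot > 0) round(100 * object@values / tot, 1) else 0,
    significant = object@significant))
})

#' @describeIn ProjectionResult mean and 95% HPD of the draws.
#' @param object a ProjectionResult.
#' @export
setMethod("show", "ProjectionResult", function(object) {
  h <- hpdInterval(object@draws)
  cat(sprintf("ProjectionResult [%s]: mean %.4f, 95%% HPD [%.4f, %.4f] (%d draws)\n",
              object@label, mean(object@draws), h[1], h[2],
              length(object@draws)))
})

#' @describeIn SelectionGradientResult coefficients on all scales.
#' @param object a SelectionGradientResult.
#' @export
setMethod("show", "SelectionGradientResult", function(object) {
  cat(sprintf("SelectionGradientResult [%s], n = %d, mean survival = %.3f\n",
              paste(object@labels, collapse = " @ "), object@n,
              object@meanSurvival))
  print(round(data.frame(logit = object@logitScale, prob = object@probScale,
                         relative = object@relScale, unit = object@unit), 4))
})

#' @describeIn DirectionVector vector, kind, and labels.
#' @param object a DirectionVector.
#' @export
setMethod("show", "DirectionVector", function(object) {
  cat(sprintf("DirectionVector [%s%s] %s\n", object@kind,
              if (object@degenerate) ", degenerate" else "",
              paste(names(object@labels), object@labels, sep = "=",
                    collapse = " ")))
  print(round(object@vector, 5))
})
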