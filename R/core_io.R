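#' @include AllGenerics.R
NULL

#' Read a phenotype table from CSV
#'
#' Validates the schema on read: required identifier/flag columns must exist,
#' individual ids must be unique, dams must nest in sires within blocks, and
#' trait cells may be missing only for unmeasured individuals.
#'
#' @param path CSV file (one header row).
#' @param traitNames trait column names; by default every column that is not
#'   an identifier or flag column is treated as a trait.
#' @return a [PhenotypeTable-class].
#' @export
readPhenotypes <- function(path, traitNames = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(requiredPhenoCols, names(d))
  if (length(miss))
    stop("phenotype file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(traitNames))
    traitNames <- setdiff(names(d), requiredPhenoCols)
  if (!length(traitNames)) stop("no trait columns found")
  for (id in c("individual_id", "sire_id", "dam_id", "block_id", "species",
               "environment"))
    d[[id]] <- as.character(d[[id]])
  obj <- new("PhenotypeTable", data = d, traitNames = traitNames)
  validObject(obj)
  obj
}

#' Write a phenotype table to CSV
#'
#' Stable column order: identifiers, traits, flags.
#'
#' @param table a [PhenotypeTable-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePhenotypes <- function(table, path) {
  d <- as.data.frame(table)
  ord <- c(setdiff(requiredPhenoCols, c("emerged", "measured", "survived")),
           traitNames(table), c("emerged", "measured", "survived"))
  write.csv(d[, ord], path, row.names = FALSE)
  invisible(path)
}

#' Subset a phenotype table to one species x environment context
#'
#' @param table a [PhenotypeTable-class].
#' @param species,environment labels to keep (NULL = keep all).
#' @param measuredOnly drop unmeasured individuals (default FALSE).
#' @return a [PhenotypeTable-class].
#' @export
subsetContext <- function(table, species = NULL, environment = NULL,
                          measuredOnly = FALSE) {
  d <- as.data.frame(table)
  if (!is.null(species)) d <- d[d$species %in% species, , drop = FALSE]
  if (!is.null(environment))
    d <- d[d$environment %in% environment, , drop = FALSE]
  if (measuredOnly) d <- d[d$measured == 1, , drop = FALSE]
  rownames(d) <- NULL
  new("PhenotypeTable", data = d, traitNames = traitNames(table))
}

#' Reference means for mean standardization
#'
#' Mean standardization divides each trait by a reference mean so that
#' (co)variances are on the evolvability scale and comparable across traits.
#' The default reference is the per-species grand mean across all
#' environments, so environment-to-environment differences in standardized
#' means (plasticity) are preserved; a per-context reference would force
#' every standardized context mean to 1 and erase plasticity vectors.
#'
#' @param table a [PhenotypeTable-class] (measured individuals are used).
#' @param source "species" (default), "context", or "user".
#' @param means for `source = "user"`: named list per species of per-trait
#'   reference means.
#' @return a [StandardizationReference-class].
#' @export
standardizationReference <- function(table, source = c("species", "context",
                                                       "user"),
                                     means = NULL) {
  source <- match.arg(source)
  tn <- traitNames(table)
  if (source == "user") {
    if (is.null(means)) stop("user source requires explicit means")
    return(new("StandardizationReference", means = means, source = source))
  }
  d <- as.data.frame(subsetContext(table, measuredOnly = TRUE))
  key <- if (source == "species") d$species else
    paste(d$species, d$environment, sep = "@")
  m <- lapply(split(d[, tn, drop = FALSE], key), colMeans)
  new("StandardizationReference", means = m, source = source)
}

#' Mean standardize trait values
#'
#' Divides each trait by its reference mean. With the default per-species
#' grand-mean reference, the species-wide mean of each standardized trait is
#' exactly 1 and variances become evolvabilities (variance / mean^2).
#'
#' @param table a [PhenotypeTable-class].
#' @param ref a [StandardizationReference-class]; default computed from the
#'   table itself (per-species grand means).
#' @return the standardized [PhenotypeTable-class].
#' @export
meanStandardize <- function(table, ref = NULL) {
  if (is.null(ref)) ref <- standardizationReference(table)
  tn <- traitNames(table)
  d <- as.data.frame(table)
  key <- if (ref@source == "context")
    paste(d$species, d$environment, sep = "@") else d$species
  for (k in unique(key)) {
    if (is.null(ref@means[[k]]))
      stop("no reference means for group '", k, "'")
    m <- ref@means[[k]][tn]
    if (any(!is.finite(m) | m == 0))
      stop("zero or missing reference mean; division unstable")
    rows <- key == k
    for (j in seq_along(tn)) {
      x <- d[rows, tn[j]]
      if (m[j] < 0 && all(x[!is.na(x)] > 0))
        stop("negative reference mean for strictly positive trait '",
             tn[j], "'")
      d[rows, tn[j]] <- x / m[j]
    }
  }
  new("PhenotypeTable", data = d, traitNames = tn)
}

#' Per-group trait means
#'
#' Arithmetic mean of each trait per group, measured individuals only.
#'
#' @param table a [PhenotypeTable-class].
#' @param by grouping columns (default species and environment).
#' @return data.frame: grouping columns then one column per trait.
#' @export
groupMeans <- function(table, by = c("species", "environment")) {
  d <- as.data.frame(subsetContext(table, measuredOnly = TRUE))
  if (!nrow(d)) stop("no measured individuals")
  tn <- traitNames(table)
  key <- interaction(d[, by, drop = FALSE], drop = TRUE, sep = "\r")
  agg <- aggregate(d[, tn, drop = FALSE], by = list(.key = key), FUN = mean)
  labs <- do.call(rbind, strsplit(as.character(agg$.key), "\r", fixed = TRUE))
  out <- data.frame(labs, stringsAsFactors = FALSE)
  names(out) <- by
  cbind(out, agg[, tn, drop = FALSE])
}

#' Extract one group's mean vector
#'
#' @param means output of [groupMeans()].
#' @param traitNames trait columns.
#' @param ... named filters, e.g. `species = "sp_A"`, `environment = "elev500"`.
#' @return named numeric trait-mean vector.
#' @export
meanVector <- function(means, traitNames, ...) {
  f <- list(...)
  rows <- rep(TRUE, nrow(means))
  for (nm in names(f)) rows <- rows & means[[nm]] == f[[nm]]
  if (sum(rows) != 1) stop("filters must select exactly one group")
  unlist(means[rows, traitNames, drop = TRUE])
}
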