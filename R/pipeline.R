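#' @include AllGenerics.R
NULL

#' Two-environment G x E scenario configurations
#'
#' Canonical constructions for testing what genotype-by-environment
#' interaction does to the genetic variance available to selection in a
#' novel environment. Selection acts on the first trait at the novel
#' environment in every scenario; the scenarios differ only in the sire
#' covariance there:
#' \describe{
#'   \item{B}{no G x E: the same sire covariance in both environments.}
#'   \item{C}{G x E increases genetic variance in the direction of
#'     selection at the novel environment.}
#'   \item{D}{G x E decreases genetic variance in the direction of
#'     selection at the novel environment.}
#' }
#'
#' @param scenario "B", "C" or "D".
#' @param nBlocks crossing blocks (default 8).
#' @param offspringPerFamilyPerEnv offspring per family per environment.
#' @param seed master seed.
#' @param species species label.
#' @return a [SimConfig-class] with environments `c("native", "novel")` and
#'   three traits.
#' @export
scenarioConfig <- function(scenario = c("B", "C", "D"), nBlocks = 8L,
                           offspringPerFamilyPerEnv = 8L, seed = 1L,
                           species = "sp_A") {
  scenario <- match.arg(scenario)
  lo <- diag(c(0.08, 0.40, 0.20))   # little variance along selection (e1)
  hi <- diag(c(0.40, 0.40, 0.20))   # abundant variance along selection
  eq <- diag(c(0.30, 0.30, 0.20))
  Gs <- switch(scenario,
               B = list(native = eq, novel = eq),
               C = list(native = lo, novel = hi),
               D = list(native = hi, novel = lo))
  simConfig(
    nBlocks = nBlocks, environments = c("native", "novel"),
    offspringPerFamilyPerEnv = offspringPerFamilyPerEnv,
    traitNames = c("trait1", "trait2", "trait3"),
    mu = list(native = c(1, 1, 1), novel = c(1.1, 0.9, 1)),
    SigmaSire = Gs, SigmaDam = diag(0.05, 3), sigma2Block = 0.01,
    SigmaResid = diag(0.3, 3), rhoGE = 0.5,
    betaSurvival = list(intercept = 0, beta = c(1.5, 0, 0)),
    premeasurementMortality = 0.1, familyDropout = 0,
    species = species, seed = seed)
}

#' Write small fixture datasets
#'
#' Three tiny (< 500 row) phenotype CSVs spanning the no-G-x-E,
#' variance-increasing and variance-decreasing scenarios of
#' [scenarioConfig()], for tests and documentation. Deterministic per seed,
#' and each file passes [readPhenotypes()] validation.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return named character vector of the three file paths.
#' @export
makeFixtures <- function(dir = tempdir(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(B = file.path(dir, "scenario_B.csv"),
             C = file.path(dir, "scenario_C.csv"),
             D = file.path(dir, "scenario_D.csv"))
  for (sc in names(paths)) {
    cfg <- scenarioConfig(sc, nBlocks = 2L, offspringPerFamilyPerEnv = 3L,
                          seed = deriveSeed(seed, paste0("fixture", sc)))
    writePhenotypes(simulateDataset(cfg), paths[[sc]])
  }
  paths
}

logStage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# translate a YAML/list `simulate` block into a SimConfig; scalar covariance
# entries mean "that value times the identity"
configFromList <- function(x) {
  p <- length(x$traitNames %||% c("complexity", "indent_width",
                                  "indent_number", "SLA", "flavonol"))
  for (nm in c("SigmaSire", "SigmaDam", "SigmaResid"))
    if (!is.null(x[[nm]]) && is.numeric(x[[nm]]) && length(x[[nm]]) == 1)
      x[[nm]] <- diag(x[[nm]], p)
  do.call(simConfig, x[intersect(names(x), names(formals(simConfig)))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> mean standardize -> fit the half-sib
#' model per species x environment context -> eigenanalysis and angles
#' between leading eigenvectors (native vs. other environments) -> genetic
#' covariance tensor (with breeding-value randomization nulls when
#' `nSim > 0`) -> D-matrix -> plasticity, selection and native-phenotype
#' projections through G. Writes a JSON report (and the phenotype CSV when
#' simulated) to `outDir`; identical seeds give identical reports.
#'
#' @param config a list, or path to a YAML file, with elements: `simulate`
#'   (list of per-species [simConfig()] argument lists) or `input` (CSV
#'   path); `nativeEnvironment` (named by species); `mcmc` (arguments of
#'   [mcmcSettings()]); `nPerm`, `nSim`, `nBoot`, `alpha`; `outDir`; `seed`.
#' @return the report, invisibly (also written as `report.json`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  outDir <- config$outDir %||% tempfile("pipeline")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha %||% 0.05
  report <- list(seed = seed)

  ## data
  if (!is.null(config$simulate)) {
    logStage("simulate", "generating %d species", length(config$simulate))
    tabs <- lapply(names(config$simulate), function(sp) {
      args <- config$simulate[[sp]]
      args$species <- sp
      args$seed <- args$seed %||% deriveSeed(seed, paste0("sim-", sp))
      simulateDataset(configFromList(args))
    })
    tab <- do.call(combinePhenotypes, tabs)
    writePhenotypes(tab, file.path(outDir, "phenotypes.csv"))
  } else if (!is.null(config$input)) {
    logStage("read", "reading %s", config$input)
    tab <- readPhenotypes(config$input)
  } else stop("config needs a 'simulate' block or an 'input' path")

  ## standardize
  logStage("standardize", "mean standardizing by per-species grand means")
  tab <- meanStandardize(tab)
  gm <- groupMeans(tab)
  tn <- traitNames(tab)
  report$groupMeans <- gm

  ## contexts
  d <- as.data.frame(tab)
  ctx <- unique(d[, c("species", "environment")])
  if (!is.null(config$contexts)) {
    want <- vapply(config$contexts, function(x)
      paste(x$species, x$environment), "")
    have <- paste(ctx$species, ctx$environment)
    missing <- setdiff(want, have)
    if (length(missing))
      stop("config references missing context(s): ",
           paste(missing, collapse = "; "))
    ctx <- ctx[have %in% want, , drop = FALSE]
  }

  mcmcArgs <- config$mcmc %||% list()
  fits <- list()
  for (i in seq_len(nrow(ctx))) {
    sp <- ctx$species[i]; env <- ctx$environment[i]
    lab <- paste(sp, env, sep = " @ ")
    logStage("fit", "half-sib model for %s", lab)
    mcmcArgs$seed <- deriveSeed(seed, paste0("fit-", lab))
    fits[[lab]] <- fitHalfsib(tab, species = sp, environment = env,
                              mcmc = do.call(mcmcSettings, mcmcArgs))
  }

  ## eigen summaries, diagnostics, angles to native environment
  natEnv <- config$nativeEnvironment
  report$contexts <- lapply(fits, function(f) {
    es <- eigenG(posteriorMean(f, "sire"))
    diag <- diagnoseChain(f)
    list(species = f@species, environment = f@environment,
         posteriorMeanG = posteriorMean(f, "sire"),
         eigenvalues = es@values, proportions = es@proportions,
         gmax = es@vectors[, 1], mixingPass = mean(diag$pass))
  })
  if (!is.null(natEnv)) {
    report$angles <- list()
    for (sp in unique(ctx$species)) {
      native <- fits[[paste(sp, natEnv[[sp]], sep = " @ ")]]
      if (is.null(native)) next
      for (env in setdiff(ctx$environment[ctx$species == sp],
                          natEnv[[sp]])) {
        f <- fits[[paste(sp, env, sep = " @ ")]]
        a <- anglePosterior(native, f)
        report$angles[[paste(sp, env, sep = " @ ")]] <-
          list(mean = a$mean, hpd = a$hpd)
      }
    }
  }

  ## nullG randomization tests
  nPerm <- config$nPerm %||% 0L
  if (nPerm > 0) {
    logStage("nulls", "randomization test, %d permutations/context", nPerm)
    report$nullG <- lapply(names(fits), function(lab) {
      f <- fits[[lab]]
      res <- nullGTest(subsetContext(tab, f@species, f@environment),
                       nPerm = nPerm, alpha = alpha, observed = f,
                       mcmc = do.call(mcmcSettings, mcmcArgs),
                       seed = deriveSeed(seed, paste0("nullg-", lab)))
      list(context = lab, significant = res$significant,
           pvalues = res$pvalues)
    })
  }

  ## covariance tensor
  if (length(fits) >= 2) {
    logStage("tensor", "covariance tensor of %d G matrices", length(fits))
    tens <- covarianceTensor(fits, labels = names(fits))
    nSim <- config$nSim %||% 0L
    if (nSim > 0) {
      logStage("tensor", "breeding-value randomization null, %d replicates",
               nSim)
      tens <- nullTensor(fits, observed = tens, nSim = nSim, alpha = alpha,
                         seed = deriveSeed(seed, "nulltensor"))
    }
    report$tensor <- list(eigenvalues = tens@values,
                          pct = 100 * tens@values /
                            max(sum(tens@values), .Machine$double.eps),
                          coordinates = tens@coordinates,
                          significant = tens@significant)
  }

  ## D matrix
  if (nrow(gm) >= 2) {
    dm <- computeD(gm, traitNames = tn)
    report$D <- list(D = dm@D, eigenvalues = dm@eigen@values,
                     scores = dm@scores)
  }

  ## projections
  nBoot <- config$nBoot %||% 100L
  if (!is.null(natEnv)) {
    report$projections <- list()
    for (sp in unique(ctx$species)) {
      nat <- natEnv[[sp]]
      natMeans <- tryCatch(meanVector(gm, tn, species = sp,
                                      environment = nat),
                           error = function(e) NULL)
      if (is.null(natMeans)) next
      for (env in setdiff(ctx$environment[ctx$species == sp], nat)) {
        lab <- paste(sp, env, sep = " @ ")
        f <- fits[[lab]]
        ## plasticity through G at the novel and the native environment
        dv <- plasticityVector(natMeans,
                               meanVector(gm, tn, species = sp,
                                          environment = env),
                               labels = c(species = sp, from = nat,
                                          to = env))
        if (!dv@degenerate) {
          for (where in c(lab, paste(sp, nat, sep = " @ "))) {
            pr <- projectPosterior(dv, fits[[where]],
                                   label = paste("plasticity", lab,
                                                 "through G", where),
                                   seed = deriveSeed(seed, paste0("proj-",
                                                                  lab, where)))
            report$projections[[paste("plasticity", lab, "|", where)]] <-
              list(mean = mean(draws(pr)), hpd = hpdInterval(draws(pr)))
          }
        }
        ## selection through G (only where estimable)
        bb <- tryCatch(
          bootstrapBeta(tab, nBoot = nBoot, species = sp, environment = env,
                        seed = deriveSeed(seed, paste0("boot-", lab))),
          error = function(e) {
            logStage("selection", "skipping %s: %s", lab,
                     conditionMessage(e))
            NULL
          })
        if (!is.null(bb) && nrow(bb)) {
          for (where in c(lab, paste(sp, nat, sep = " @ "))) {
            pr <- projectPosterior(bb, fits[[where]],
                                   label = paste("selection", lab,
                                                 "through G", where),
                                   seed = deriveSeed(seed, paste0("sproj-",
                                                                  lab, where)))
            report$projections[[paste("selection", lab, "|", where)]] <-
              list(mean = mean(draws(pr)), hpd = hpdInterval(draws(pr)))
          }
        }
      }
      ## native-phenotype direction of the other species at sp's novel edge
      for (other in setdiff(unique(ctx$species), sp)) {
        otherNat <- natEnv[[other]]
        if (is.null(otherNat)) next
        lab <- paste(sp, otherNat, sep = " @ ")
        if (is.null(fits[[lab]])) next
        om <- tryCatch(meanVector(gm, tn, species = other,
                                  environment = otherNat),
                       error = function(e) NULL)
        sm <- tryCatch(meanVector(gm, tn, species = sp,
                                  environment = otherNat),
                       error = function(e) NULL)
        if (is.null(om) || is.null(sm)) next
        nd <- nativeDirection(om, sm, environment = otherNat)
        if (nd@degenerate) next
        pr <- projectPosterior(nd, fits[[lab]],
                               label = paste("native phenotype of", other,
                                             "through G", lab),
                               seed = deriveSeed(seed, paste0("nproj-",
                                                              lab, other)))
        report$projections[[paste("native", other, "|", lab)]] <-
          list(mean = mean(draws(pr)), hpd = hpdInterval(draws(pr)))
      }
    }
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  logStage("done", "report written to %s", file.path(outDir, "report.json"))
  invisible(report)
}
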