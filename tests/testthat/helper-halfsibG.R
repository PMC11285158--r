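# shared builders for the test suite

# small single-species config; override any simConfig argument
quickConfig <- function(..., p = 3L) {
  defaults <- list(
    nBlocks = 4L, environments = c("native", "novel"),
    offspringPerFamilyPerEnv = 6L,
    traitNames = paste0("t", seq_len(p)),
    premeasurementMortality = 0, familyDropout = 0, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# deterministic 10-row table built by hand (no RNG), for I/O tests
tinyTable <- function() {
  d <- data.frame(
    individual_id = sprintf("i%02d", 1:10),
    sire_id = rep(c("S1", "S2"), each = 5),
    dam_id = rep(c("D1", "D2"), times = c(5, 5)),
    block_id = "B1",
    species = "sp_A",
    environment = rep(c("low", "high"), 5),
    t1 = seq(1, 2, length.out = 10),
    t2 = seq(4, 2, length.out = 10),
    emerged = 1L,
    measured = 1L,
    survived = rep(c(0L, 1L), 5),
    stringsAsFactors = FALSE)
  new("PhenotypeTable", data = d, traitNames = c("t1", "t2"))
}

# random symmetric PSD matrix
randomPSD <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(0.1, p)
}

fastMCMC <- function(seed = 1L, nSamples = 200L)
  mcmcSettings(nBurnin = 300L, thin = 2L, nSamples = nSamples, seed = seed)
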