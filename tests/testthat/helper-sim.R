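# shared small simulated populations; built fresh per call under the given
# seed so tests are reproducible and independent

smallConfig <- function(n_sires = 10L, dams_per_sire = 10L,
                        progeny_per_dam = 2L, n_snps = 40L,
                        n_locations = 4L, seed = 1L, ...) {
  SimConfig(n_sires = n_sires, dams_per_sire = dams_per_sire,
            progeny_per_dam = progeny_per_dam, n_snps = n_snps,
            n_locations = n_locations, seed = seed, ...)
}

# uncensored calibration regime: latent scale, no clipping in range
latentConfig <- function(..., seed = 1L) {
  SimConfig(baseline_mean = 402, censor_day = 2000L, seed = seed, ...)
}

# write a tiny hand-made PLINK text fixture; returns the two paths
writeTinyPlink <- function(dir = tempdir()) {
  pedPath <- file.path(dir, "tiny.ped")
  mapPath <- file.path(dir, "tiny.map")
  writeLines(c(
    "1 I1 0 0 0 -9 A A G G",
    "1 I2 0 0 0 -9 A G 0 0",
    "1 I3 I1 I2 0 -9 G G G A"), pedPath)
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), mapPath)
  list(ped = pedPath, map = mapPath)
}

writePhenoCsv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# balanced paternal half-sib design, single location, no cages in the model:
# used for the REML-vs-ANOVA oracle
halfSibData <- function(nSire = 30, nOff = 20, sigma2a = 400, sigma2e = 1600,
                        seed = 1) {
  set.seed(seed)
  sires <- sprintf("S%02d", seq_len(nSire))
  dams <- sprintf("D%04d", seq_len(nSire * nOff))
  off <- sprintf("O%04d", seq_len(nSire * nOff))
  sireOf <- rep(sires, each = nOff)
  ped <- Pedigree(id = c(sires, dams, off),
                  sire = c(rep(NA, nSire + nSire * nOff), sireOf),
                  dam = c(rep(NA, nSire + nSire * nOff), dams))
  aS <- rnorm(nSire, 0, sqrt(sigma2a)); names(aS) <- sires
  aD <- rnorm(length(dams), 0, sqrt(sigma2a)); names(aD) <- dams
  a <- 0.5 * (aS[sireOf] + aD) + rnorm(length(off), 0, sqrt(sigma2a / 2))
  y <- 200 + a + rnorm(length(off), 0, sqrt(sigma2e))
  list(ped = ped, ids = off, sire = sireOf, y = unname(y))
}
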