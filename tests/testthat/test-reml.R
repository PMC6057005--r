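test_that("balanced half-sib REML equals the ANOVA closed form", {
  hs <- halfSibData(nSire = 30, nOff = 20, seed = 21)
  Ainv <- buildAinv(hs$ped)
  Z <- Matrix::sparseMatrix(i = seq_along(hs$ids),
                            j = match(hs$ids, pedRecords(hs$ped)$id),
                            x = 1, dims = c(length(hs$ids), length(hs$ped)),
                            dimnames = list(hs$ids, pedRecords(hs$ped)$id))
  fit <- fitLMM(hs$y, matrix(1, length(hs$y), 1),
                blocks = list(a = list(Z = Z, Ginv = Ainv)), se = FALSE)
  # sire-model ANOVA: sigma2_s = (MS_sire - MS_within) / k, sigma2_a = 4 sigma2_s
  av <- anova(stats::aov(hs$y ~ factor(hs$sire)))
  s2s <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / 20
  expect_equal(unname(fit$varcomp["a"]), 4 * s2s, tolerance = 1e-3)
  expect_equal(unname(fit$varcomp["a"] + fit$varcomp["residual"]),
               av$`Mean Sq`[2] + s2s, tolerance = 1e-3)
})

test_that("constant phenotype drives all components to the lower bound", {
  sim <- simulateDataset(smallConfig(n_snps = 5, seed = 22))
  s <- survivalDays(sim$phenotypes)
  ph <- PhenotypeSet(s$id, rep(402L, nrow(s)), rep(TRUE, nrow(s)))
  fit <- fitNullSTM(ph, sim$cages, Ainv = buildAinv(sim$pedigree), se = FALSE)
  expect_lt(sum(varComp(fit)), 1e-4)
})

test_that("STM REML recovers the generative variance components", {
  # full 48-sire, 1,920-hen design; polygenic and cage variance are only
  # weakly separated in family cages, so recovery is judged against the
  # asymptotic (posterior) SDs of a single fit, as is standard for this
  # design
  reps <- 10
  est <- matrix(NA_real_, reps, 3)
  ses <- matrix(NA_real_, 2, 3)
  for (r in seq_len(reps)) {
    cfg <- latentConfig(n_snps = 2, seed = 400 + r)
    sim <- simulateDataset(cfg)
    fit <- fitNullSTM(sim$phenotypes, sim$cages,
                      Ainv = buildAinv(sim$pedigree, inbreeding = "zero"),
                      se = (r <= 2))
    est[r, ] <- varComp(fit)[c("a", "cage", "residual")]
    if (r <= 2) ses[r, ] <- fit@varcompSE[c("a", "cage", "residual")]
  }
  truth <- c(576, 763, 6306)
  mu <- colMeans(est)
  seBar <- colMeans(ses)
  for (k in 1:3) expect_lt(abs(mu[k] - truth[k]), 2 * seBar[k])
  # phenotypic variance near the study magnitude
  expect_lt(abs(sum(mu) / 7645 - 1), 0.05)
})

test_that("GLS scan equals the naive dense per-SNP solve", {
  cfg <- SimConfig(n_sires = 6, dams_per_sire = 5, progeny_per_dam = 2,
                   n_snps = 12, n_locations = 3, seed = 23, maf_low = 0.25,
                   qtl = data.frame(snp = 4, beta_D = 25, beta_I = 5, freq = 0.4))
  sim <- simulateDataset(cfg)
  Ainv <- buildAinv(sim$pedigree)
  fit <- fitNullSTM(sim$phenotypes, sim$cages, Ainv = Ainv)
  sc <- scanTable(scanSTM(fit, sim$geno))

  # independent oracle: explicit dense covariance, textbook GLS per SNP
  vc <- varComp(fit)
  s <- survivalDays(sim$phenotypes)
  A <- buildA(sim$pedigree)[s$id, s$id]
  mem <- cageMembers(sim$cages)
  cg <- mem$cage[match(s$id, mem$id)]
  J <- outer(cg, cg, "==") + 0
  V <- vc["a"] * A + vc["cage"] * J + vc["residual"] * diag(nrow(s))
  Vi <- solve(V)
  loc <- factor(mem$location[match(s$id, mem$id)])
  X0 <- model.matrix(~loc)
  cv <- snpCovariates(sim$geno, sim$cages, ids = s$id)
  for (j in c(1, 4, 9)) {
    X <- cbind(X0, cv$direct[, j], cv$indirect[, j])
    XtVi <- t(X) %*% Vi
    cf <- solve(XtVi %*% X, XtVi %*% s$survivalDay)
    covb <- solve(XtVi %*% X)
    k <- ncol(X)
    expect_equal(sc$beta_D[j], cf[k - 1], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sc$beta_I[j], cf[k], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sc$se_D[j], sqrt(covb[k - 1, k - 1]), tolerance = 1e-8)
    expect_equal(sc$se_I[j], sqrt(covb[k, k]), tolerance = 1e-8)
  }
})

test_that("with a near-identity covariance GLS reduces to OLS", {
  # spec fixture: x = (0,1,1,2), y = (10,12,14,18), intercept -> slope 4
  y <- c(10, 12, 14, 18)
  x <- c(0, 1, 1, 2)
  Z <- Matrix::sparseMatrix(i = 1:4, j = rep(1, 4), x = 1, dims = c(4, 1))
  fit <- fitLMM(y, matrix(1, 4, 1), blocks = list(g = list(Z = Z, Ginv = NULL)),
                se = FALSE)
  # the dummy shared random effect is indistinguishable from the intercept
  # and collapses to the bound, leaving V proportional to the identity
  g <- glsFixed(fit$engine, cbind(x))
  expect_equal(g$beta[1], 4, tolerance = 1e-6)
})

test_that("RMM null fit recovers components from its own generative form", {
  set.seed(24)
  cfg <- SimConfig(n_sires = 10, dams_per_sire = 10, progeny_per_dam = 2,
                   n_snps = 2, n_locations = 2, seed = 24)
  pop <- simulatePopulation(cfg)
  mem <- cageMembers(pop$cages)
  ids <- mem$id
  n <- length(ids); nm <- 13
  rec <- pedRecords(pop$pedigree)
  # simulate directly from the random-regression model
  s2 <- c(a = 4e-4, pe = 3e-4, cageSlope = 2e-4, cageMonth = 0.01, e = 0.04)
  aAll <- numeric(nrow(rec)); names(aAll) <- rec$id
  founders <- is.na(rec$sire)
  aAll[founders] <- rnorm(sum(founders), 0, sqrt(s2["a"]))
  kids <- which(!founders)
  aAll[kids] <- 0.5 * (aAll[rec$sire[kids]] + aAll[rec$dam[kids]]) +
    rnorm(length(kids), 0, sqrt(s2["a"] / 2))
  pe <- rnorm(n, 0, sqrt(s2["pe"]))
  cgF <- factor(mem$cage)
  ct <- rnorm(nlevels(cgF), 0, sqrt(s2["cageSlope"]))
  y <- matrix(0, n, nm, dimnames = list(ids, NULL))
  for (m in seq_len(nm)) {
    ckm <- rnorm(nlevels(cgF), 0, sqrt(s2["cageMonth"]))
    y[, m] <- 0.95 - 0.02 * m + m * (aAll[ids] + pe + ct[as.integer(cgF)]) +
      ckm[as.integer(cgF)] + rnorm(n, 0, sqrt(s2["e"]))
  }
  fit <- fitNullRMM(y, pop$cages, Ainv = buildAinv(pop$pedigree),
                    polyOrder = 2, residLower = 1e-4, se = TRUE)
  vc <- varComp(fit); vse <- fit@varcompSE
  for (nmv in c("a", "pe", "cageMonth")) {
    tol <- 2 * vse[nmv] + 0.35 * s2[nmv]   # 2 SE with Monte-Carlo slack
    expect_lt(abs(vc[nmv] - s2[nmv]), tol)
  }
  expect_lt(abs(mean(vc[grep("residual", names(vc))]) - s2["e"]),
            2 * mean(vse[grep("residual", names(vse))], na.rm = TRUE) + 0.01)
})

test_that("RMM fixed curve reproduces the final-month survival fraction", {
  sim <- simulateDataset(SimConfig(n_sires = 16, baseline_mean = 256,
                                   n_snps = 2, seed = 25))
  mr <- monthlyRecords(sim$phenotypes)
  fit <- fitNullRMM(mr, sim$cages,
                    Ainv = buildAinv(sim$pedigree, inbreeding = "zero"))
  eng <- fit@engine
  last <- eng$ctx$tvec == max(eng$ctx$tvec)
  fitted13 <- mean(eng$X[last, , drop = FALSE] %*% fixedEffects(fit))
  expect_lt(abs(fitted13 - mean(mr[, 13])), 0.02)
})

test_that("GLMM null fit behaves like its oracles at the boundaries", {
  sim <- simulateDataset(smallConfig(n_snps = 6, seed = 26,
                                     baseline_mean = 256))
  mr <- monthlyRecords(sim$phenotypes)
  Ainv <- buildAinv(sim$pedigree)
  # zero-variance PQL equals ordinary logistic regression
  fg <- fitNullGLMM(mr, sim$cages, Ainv = Ainv, polyOrder = 3,
                    varFixed = c(a = 0, cageMonth = 0, pe = 0))
  gl <- glm.fit(fg@engine$X, fg@engine$ctx$y01, family = binomial())
  expect_equal(unname(fixedEffects(fg)), unname(gl$coefficients),
               tolerance = 1e-6)
  # all-survivors dataset: separation clamp triggers and is logged
  s <- survivalDays(sim$phenotypes)
  phAll <- PhenotypeSet(s$id, rep(402L, nrow(s)), rep(TRUE, nrow(s)))
  mrAll <- monthlyRecords(phAll)
  expect_message(
    fitNullGLMM(mrAll, sim$cages, Ainv = Ainv, polyOrder = 1, maxitPQL = 15),
    "clamped")
})

test_that("scans never modify the null fit they borrow the covariance from", {
  sim <- simulateDataset(smallConfig(n_snps = 10, seed = 27))
  fit <- fitNullSTM(sim$phenotypes, sim$cages, Ainv = buildAinv(sim$pedigree))
  vc0 <- varComp(fit); fe0 <- fixedEffects(fit)
  invisible(scanSTM(fit, sim$geno))
  expect_identical(varComp(fit), vc0)
  expect_identical(fixedEffects(fit), fe0)
})
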