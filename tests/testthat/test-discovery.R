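test_that("q-values: degenerate, hand-computed and BH-limit cases", {
  r1 <- estimateQvalues(rep(1, 20))
  expect_equal(r1$q, rep(1, 20))
  expect_equal(r1$pi0, 1)

  # hand calculation in the pi0 = 1 (Benjamini-Hochberg) limit
  r2 <- estimateQvalues(c(0.01, 0.04, 0.9), pi0 = 1)
  expect_equal(r2$q, c(0.03, 0.06, 0.9))

  # BH limit holds exactly on arbitrary inputs
  set.seed(41)
  for (m in c(7, 50, 1000)) {
    p <- runif(m)^1.5
    expect_equal(estimateQvalues(p, pi0 = 1)$q, p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }

  # uniform nulls: smoother pi0 lands near 1
  set.seed(42)
  r3 <- estimateQvalues(runif(10000))
  expect_gte(r3$pi0, 0.9); expect_lte(r3$pi0, 1)

  # monotonicity: sorting by p never decreases q
  p <- runif(500)
  q <- estimateQvalues(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-12))

  expect_error(estimateQvalues(numeric(0)), "empty")
  expect_error(estimateQvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("candidate selection maps q < 0.3 to an implied p threshold", {
  k <- 40
  set.seed(43)
  tab <- data.frame(snp_id = paste0("s", 1:k), chrom = "1", pos = 1:k,
                    maf = 0.3, beta_D = 0, se_D = 1, stat_D = 0,
                    p_D = runif(k), p_D_gc = NA_real_, q_D = NA_real_,
                    beta_I = 0, se_I = 1, stat_I = 0, p_I = runif(k),
                    p_I_gc = NA_real_, q_I = NA_real_, model = "STM")
  # without genomic control the selection refuses to run
  sc0 <- new("ScanResult", table = tab, model = "STM", gc = list())
  expect_error(selectCandidates(sc0), "genomicControl")

  tab$p_D_gc <- tab$p_D; tab$p_I_gc <- tab$p_I
  # flat p-values: nothing passes, threshold undefined (as in W1 * WC)
  sc1 <- new("ScanResult", table = tab, model = "STM", gc = list())
  sel1 <- selectCandidates(sc1, qThr = 0.3, pi0 = 1)
  expect_equal(nrow(sel1$candidates), 0L)
  expect_true(is.na(sel1$pThreshold))

  # a planted strong effect is selected; threshold = largest passing p
  tab$p_D_gc[5] <- 1e-8
  sc2 <- new("ScanResult", table = tab, model = "STM", gc = list())
  sel2 <- selectCandidates(sc2, qThr = 0.3, pi0 = 1)
  expect_true("s5" %in% sel2$candidates$snp_id)
  expect_equal(sel2$pThreshold, max(sel2$candidates$p))
  # q boundary: q = 0.29 is selected, q >= 0.3 is not
  expect_true(all(sel2$candidates$q < 0.3))
})

test_that("backwards elimination resolves perfect LD to a single copy", {
  cfg <- latentConfig(n_snps = 60, seed = 44,
                      qtl = data.frame(snp = 20, beta_D = 28, beta_I = 0,
                                       freq = 0.4),
                      ld_duplicate_qtl = TRUE)
  sim <- simulateDataset(cfg)
  expect_identical(dosages(sim$geno)[, 20], dosages(sim$geno)[, 21])
  fit <- fitNullSTM(sim$phenotypes, sim$cages,
                    Ainv = buildAinv(sim$pedigree, inbreeding = "zero"),
                    se = FALSE)
  sel <- selectCandidates(genomicControl(scanSTM(fit, sim$geno)), qThr = 0.3)
  el <- backwardEliminate(fit, sim$geno, sel$candidates, sel$pThreshold)
  ret <- retainedEffects(el)
  dup <- ret$snp_id %in% c("snp00020", "snp00021") & ret$effect == "direct"
  expect_equal(sum(dup), 1L)  # exactly one member of the LD pair survives
  expect_true(any(el@trace$reason == "collinear"))
  # soundness: every retained joint p at or below the threshold
  expect_true(all(ret$p <= el@pThreshold + 1e-12))
  # V = 2p(1-p)alpha^2 holds exactly for the stored fields
  expect_equal(ret$V_days2,
               2 * ret$p_major * (1 - ret$p_major) * ret$alpha_days^2)
})

test_that("elimination retains strong causal effects and stays bounded", {
  causal <- c(10L, 30L, 50L, 70L, 90L)
  strong <- causal[-1]           # beta >= 20 days
  okStrong <- 0L; fp <- integer(0)
  for (r in 1:5) {
    # effect sizes and allele frequencies in the range reported for the
    # retained direct effects in the real crosses
    cfg <- latentConfig(n_snps = 100, seed = 440 + r,
                        qtl = data.frame(snp = causal,
                                         beta_D = c(16, 20, 26, 30, 35),
                                         beta_I = 0,
                                         freq = c(0.34, 0.32, 0.35, 0.47,
                                                  0.22)))
    sim <- simulateDataset(cfg)
    fit <- fitNullSTM(sim$phenotypes, sim$cages,
                      Ainv = buildAinv(sim$pedigree, inbreeding = "zero"),
                      se = FALSE)
    sel <- selectCandidates(genomicControl(scanSTM(fit, sim$geno)), qThr = 0.3)
    el <- backwardEliminate(fit, sim$geno, sel$candidates, sel$pThreshold)
    ret <- retainedEffects(el)
    retD <- match(ret$snp_id[ret$effect == "direct"], snpMap(sim$geno)$snp)
    okStrong <- okStrong + all(strong %in% retD)
    fp <- c(fp, length(setdiff(retD, causal)))
    # trace soundness: every drop was the current maximum failing p
    expect_true(all(ret$p <= el@pThreshold + 1e-12))
  }
  expect_gte(okStrong, 4L)        # >= 80% of replicates keep all strong QTLs
  expect_lte(mean(fp), 2)         # FDR 0.3 admits only a few false effects
})

test_that("single passing candidate and empty candidate sets work", {
  sim <- simulateDataset(latentConfig(n_snps = 30, seed = 45,
                                      qtl = data.frame(snp = 7, beta_D = 30,
                                                       beta_I = 0, freq = 0.4)))
  fit <- fitNullSTM(sim$phenotypes, sim$cages,
                    Ainv = buildAinv(sim$pedigree, inbreeding = "zero"),
                    se = FALSE)
  sc <- genomicControl(scanSTM(fit, sim$geno))
  one <- data.frame(snp_id = "snp00007", effect = "direct",
                    p = scanTable(sc)$p_D_gc[7], q = 0.01)
  el <- backwardEliminate(fit, sim$geno, one, pThreshold = one$p * 1.0001)
  expect_equal(nrow(retainedEffects(el)), 1L)
  expect_equal(retainedEffects(el)$snp_id, "snp00007")
  el0 <- backwardEliminate(fit, sim$geno, one[0, ], pThreshold = NA_real_)
  expect_equal(nrow(retainedEffects(el0)), 0L)
})

test_that("variance-explained accounting matches the closed form", {
  expect_equal(varianceExplained(0.5, 10), 50)
  expect_equal(varianceExplained(c(0, 1), 35), c(0, 0))
  expect_equal(varianceExplained(0.47, 35), 2 * 0.47 * 0.53 * 1225)
  expect_lt(abs(varianceExplained(0.47, 35) - 610.3), 0.05)

  pr <- explainedProportions(209, 7645, 576)
  expect_equal(round(pr$pctP, 1), 2.7)
  expect_equal(round(pr$pctA, 1), 36.3)
  expect_equal(explainedProportions(0, 100, 10), list(pctP = 0, pctA = 0))
  expect_error(explainedProportions(1, 0, 10), "denominators")
  # ratios above 100% are permitted (upward bias under selection is a
  # documented property, not an error)
  expect_gt(explainedProportions(800, 7645, 576)$pctA, 100)
})
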