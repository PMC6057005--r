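#' Simulation configuration for the half-sib cage design
#'
#' Defaults reproduce the layout and genetic parameters of a single
#' crossbred layer line: 48 sires each mated to 20 dams with ~2 female
#' offspring per dam (1,920 hens, 384 single-sire cages of 5), a ~30,000 SNP
#' panel, survival on a 402-day laying period split into 13 monthly records,
#' and survival-time variance components sigma2_a = 576, sigma2_cage = 763,
#' sigma2_e = 6306 days^2 (phenotypic variance 7,645 days^2).
#'
#' @param n_sires,dams_per_sire,progeny_per_dam mating design counts.
#' @param cage_size members per cage (>= 2); all cage mates share a sire.
#' @param n_snps biallelic SNP panel size (no linkage disequilibrium between
#'   SNPs; see \code{ld_duplicate_qtl}).
#' @param maf_low,maf_high founder counted-allele frequency range in
#'   (0, 0.5].
#' @param qtl data.frame with columns \code{snp} (column index), \code{beta_D}
#'   (days per own allele copy), \code{beta_I} (days per cage-mate allele
#'   copy) and optionally \code{freq} (founder allele frequency override).
#' @param sigma2_a,sigma2_cage,sigma2_e polygenic, cage and residual
#'   variances in days^2.
#' @param baseline_mean intercept of the latent survival time (days).
#' @param censor_day recording-period length; latent values are clipped to
#'   [1, censor_day] and values at the cap are censored. Set large (e.g.
#'   5000) for an uncensored calibration regime.
#' @param n_months monthly binary records per hen.
#' @param n_locations number of wing-row-level location classes; cages are
#'   assigned uniformly.
#' @param location_effects fixed effect per location class (days); default an
#'   even grid on [-10, 10].
#' @param missing_rate genotype missingness injected by
#'   \code{\link{injectMissing}}.
#' @param ld_duplicate_qtl if TRUE each QTL column is duplicated into the
#'   following SNP column to create a perfect-LD pair (for elimination
#'   tests).
#' @param seed integer seed controlling all randomness.
#' @return object of class \code{SimConfig} (validated list).
#' @export
SimConfig <- function(n_sires = 48L, dams_per_sire = 20L, progeny_per_dam = 2L,
                      cage_size = 5L, n_snps = 30000L,
                      maf_low = 0.01, maf_high = 0.5,
                      qtl = NULL,
                      sigma2_a = 576, sigma2_cage = 763, sigma2_e = 6306,
                      baseline_mean = 365, censor_day = 402L, n_months = 13L,
                      n_locations = 24L, location_effects = NULL,
                      missing_rate = 0.04, ld_duplicate_qtl = FALSE,
                      seed = 1L) {
  if (cage_size < 2) stop("cage_size must be >= 2")
  if (any(c(sigma2_a, sigma2_cage, sigma2_e) < 0)) stop("variances must be >= 0")
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high)
    stop("maf bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    stopifnot(all(c("snp", "beta_D", "beta_I") %in% names(qtl)))
    if (any(qtl$snp > n_snps)) stop("qtl snp index exceeds n_snps")
  }
  if (is.null(location_effects))
    location_effects <- if (n_locations > 1)
      seq(-10, 10, length.out = n_locations) else 0
  structure(list(
    n_sires = as.integer(n_sires), dams_per_sire = as.integer(dams_per_sire),
    progeny_per_dam = as.integer(progeny_per_dam),
    cage_size = as.integer(cage_size), n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high, qtl = qtl,
    sigma2_a = sigma2_a, sigma2_cage = sigma2_cage, sigma2_e = sigma2_e,
    baseline_mean = baseline_mean, censor_day = censor_day,
    n_months = as.integer(n_months), n_locations = as.integer(n_locations),
    location_effects = location_effects, missing_rate = missing_rate,
    ld_duplicate_qtl = isTRUE(ld_duplicate_qtl), seed = as.integer(seed)),
    class = "SimConfig")
}

#' Simulate the mating design and cage layout
#'
#' Founder sires and dams are randomly mated (each dam to one sire); female
#' offspring of one sire are grouped into single-sire cages of
#' \code{cage_size} (half- or full-sibs). Offspring of a sire that do not
#' fill a complete cage are dropped with a message.
#'
#' @param config a \code{\link{SimConfig}}.
#' @return list with \code{pedigree} (\linkS4class{Pedigree}; caged offspring
#'   have generation 1), \code{cages} (\linkS4class{CageLayout}).
#' @export
simulatePopulation <- function(config) {
  set.seed(config$seed)
  ns <- config$n_sires; nd <- config$dams_per_sire; np <- config$progeny_per_dam
  sires <- sprintf("S%03d", seq_len(ns))
  dams <- sprintf("D%04d", seq_len(ns * nd))
  damSire <- rep(sires, each = nd)           # random mating: one sire per dam

  offSire <- rep(damSire, each = np)
  offDam <- rep(dams, each = np)
  off <- sprintf("H%05d", seq_along(offSire))

  # cage assembly within sire family: shuffle a sire's offspring across its
  # dams, fill complete cages, drop the remainder
  perSire <- nd * np
  nCage <- perSire %/% config$cage_size
  cage <- rep(NA_character_, length(off))
  for (s in sires) {
    ix <- sample(which(offSire == s))
    kept <- ix[seq_len(nCage * config$cage_size)]
    cage[kept] <- rep(sprintf("C_%s_%02d", s, seq_len(nCage)),
                      each = config$cage_size)
  }
  caged <- which(!is.na(cage))
  dropped <- length(off) - length(caged)
  if (dropped > 0)
    message(sprintf("simulatePopulation: dropped %d offspring not filling a cage",
                    dropped))

  cageIds <- unique(cage[caged])
  loc <- sprintf("L%02d", sample.int(config$n_locations, length(cageIds),
                                     replace = TRUE))
  ped <- Pedigree(id = c(sires, dams, off),
                  sire = c(rep(NA, ns + ns * nd), offSire),
                  dam = c(rep(NA, ns + ns * nd), offDam))
  cages <- CageLayout(off[caged], cage[caged],
                      location = data.frame(cage = cageIds, location = loc),
                      cageSize = config$cage_size)
  list(pedigree = ped, cages = cages)
}

#' Gene-drop genotypes through the pedigree
#'
#' Founder counted-allele frequencies are drawn uniformly in
#' [\code{maf_low}, \code{maf_high}] (QTL rows may pin a frequency);
#' founders are in Hardy-Weinberg proportions and each offspring receives one
#' allele from each parent by fair Mendelian sampling, independently per SNP
#' (no linkage disequilibrium).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param config a \code{\link{SimConfig}}.
#' @return list with \code{geno} (\linkS4class{GenotypeMatrix} over all
#'   pedigree members) and \code{freq} (founder frequencies used).
#' @export
dropGenotypes <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  rec <- pedRecords(pedigree)
  n <- nrow(rec); m <- config$n_snps
  freq <- stats::runif(m, config$maf_low, config$maf_high)
  if (!is.null(config$qtl) && "freq" %in% names(config$qtl)) {
    k <- !is.na(config$qtl$freq)
    freq[config$qtl$snp[k]] <- config$qtl$freq[k]
  }

  ord <- order(rec$generation)
  g <- matrix(0L, n, m)
  founders <- ord[is.na(rec$sire[ord]) & is.na(rec$dam[ord])]
  nf <- length(founders)
  g[founders, ] <- matrix(stats::rbinom(nf * m, 2L, rep(freq, each = nf)), nf, m)
  nonf <- ord[!(ord %in% founders)]
  si <- match(rec$sire[nonf], rec$id)
  di <- match(rec$dam[nonf], rec$id)
  for (gen in sort(unique(rec$generation[nonf]))) {
    sel <- which(rec$generation[nonf] == gen)
    ix <- nonf[sel]
    ps <- g[si[sel], , drop = FALSE] / 2      # transmission prob from sire
    pd <- g[di[sel], , drop = FALSE] / 2
    g[ix, ] <- matrix(stats::rbinom(length(ps), 1L, ps), length(ix), m) +
               matrix(stats::rbinom(length(pd), 1L, pd), length(ix), m)
  }
  if (config$ld_duplicate_qtl && !is.null(config$qtl)) {
    dup <- pmin(config$qtl$snp + 1L, m)
    g[, dup] <- g[, config$qtl$snp]
    freq[dup] <- freq[config$qtl$snp]
  }
  storage.mode(g) <- "numeric"
  rownames(g) <- rec$id
  colnames(g) <- sprintf("snp%05d", seq_len(m))
  map <- SnpMap(snp = colnames(g),
                chrom = as.character(1 + (seq_len(m) - 1) %/% 1000),
                pos = 1000L * (((seq_len(m) - 1) %% 1000) + 1L),
                counted = "A")
  list(geno = GenotypeMatrix(g, map = map), freq = freq)
}

#' Simulate survival phenotypes under the direct/indirect linear model
#'
#' Latent survival time = baseline + location effect + sum over QTLs of
#' (beta_D * own dosage + beta_I * summed cage-mate dosages) + polygenic
#' value a_i + cage effect + residual. Polygenic values follow parental
#' averages with Mendelian-sampling variance so var(a) = A sigma2_a; cage
#' and residual effects are iid normal. Values are clipped to
#' [1, censor_day], rounded to whole days, and records at the cap are
#' flagged censored.
#'
#' @param geno \linkS4class{GenotypeMatrix} covering all cage members (no
#'   missing entries; inject missingness afterwards with
#'   \code{\link{injectMissing}}).
#' @param cages \linkS4class{CageLayout}.
#' @param pedigree \linkS4class{Pedigree}.
#' @param config \code{\link{SimConfig}}.
#' @return list with \code{phenotypes} (\linkS4class{PhenotypeSet} over caged
#'   individuals) and \code{truth} (list: per-individual polygenic values
#'   \code{a}, per-cage effects \code{cage}, QTL table with realized
#'   \code{beta_D}, \code{beta_I}, latent values \code{latent}).
#' @export
simulateSurvival <- function(geno, cages, pedigree, config) {
  set.seed(config$seed + 2L)
  rec <- pedRecords(pedigree)
  d <- dosages(geno)
  if (anyNA(d)) stop("genotypes must be complete; use injectMissing() afterwards")

  # polygenic values by generation: founders N(0, sigma2_a), offspring
  # parental average + Mendelian sampling N(0, sigma2_a/2) (non-inbred parents)
  a <- numeric(nrow(rec)); names(a) <- rec$id
  for (gen in sort(unique(rec$generation))) {
    ix <- which(rec$generation == gen)
    si <- match(rec$sire[ix], rec$id); di <- match(rec$dam[ix], rec$id)
    founder <- is.na(si) & is.na(di)
    a[ix[founder]] <- stats::rnorm(sum(founder), 0, sqrt(config$sigma2_a))
    if (any(!founder)) {
      pa <- 0.5 * (a[si[!founder]] + a[di[!founder]])
      a[ix[!founder]] <- pa + stats::rnorm(sum(!founder), 0,
                                           sqrt(0.5 * config$sigma2_a))
    }
  }

  mem <- cageMembers(cages)
  cageIds <- unique(mem$cage)
  cageEff <- stats::rnorm(length(cageIds), 0, sqrt(config$sigma2_cage))
  names(cageEff) <- cageIds
  locEff <- config$location_effects
  names(locEff) <- sprintf("L%02d", seq_along(locEff))

  y <- config$baseline_mean +
    unname(locEff[mem$location]) +
    a[mem$id] +
    cageEff[mem$cage] +
    stats::rnorm(nrow(mem), 0, sqrt(config$sigma2_e))

  if (!is.null(config$qtl)) {
    for (k in seq_len(nrow(config$qtl))) {
      snp <- config$qtl$snp[k]
      own <- d[mem$id, snp]
      csum <- tapply(own, mem$cage, sum)
      mates <- csum[mem$cage] - own
      y <- y + config$qtl$beta_D[k] * own + config$qtl$beta_I[k] * unname(mates)
    }
  }

  latent <- y
  day <- round(pmin(pmax(y, 1), config$censor_day))
  censored <- day >= config$censor_day
  phen <- PhenotypeSet(mem$id, day, censored, censorDay = config$censor_day,
                       nMonths = config$n_months)
  list(phenotypes = phen,
       truth = list(a = a, cage = cageEff, qtl = config$qtl,
                    latent = stats::setNames(latent, mem$id)))
}

#' Inject genotype missingness
#'
#' Entries are set missing independently at \code{rate}; optionally a set of
#' individuals (e.g. early deaths never blood-sampled) loses all calls.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param rate entry-wise missing probability in [0, 1] (default from
#'   \code{config}).
#' @param config optional \code{\link{SimConfig}} supplying rate and seed.
#' @param wholeIndividuals character ids to blank entirely.
#' @return the modified \linkS4class{GenotypeMatrix}.
#' @export
injectMissing <- function(geno, rate = NULL, config = NULL,
                          wholeIndividuals = character()) {
  if (is.null(rate)) {
    if (is.null(config)) stop("supply rate or config")
    rate <- config$missing_rate
  }
  if (rate < 0 || rate > 1) stop("missing rate must be in [0, 1]")
  if (!is.null(config)) set.seed(config$seed + 3L)
  d <- dosages(geno)
  if (rate > 0)
    d[matrix(stats::runif(length(d)) < rate, nrow(d))] <- NA
  if (length(wholeIndividuals))
    d[rownames(d) %in% wholeIndividuals, ] <- NA
  GenotypeMatrix(d, map = geno@map, imputed = FALSE)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running \code{\link{simulatePopulation}},
#' \code{\link{dropGenotypes}}, \code{\link{simulateSurvival}} and
#' \code{\link{injectMissing}}. When \code{outPrefix} is given, writes
#' \code{<prefix>.ped}, \code{<prefix>.map}, \code{<prefix>_pheno.csv} and
#' \code{<prefix>_truth.tsv}.
#'
#' @param config a \code{\link{SimConfig}}.
#' @param missing apply \code{injectMissing} at \code{config$missing_rate}.
#' @param outPrefix optional output path prefix.
#' @return list with pedigree, cages, geno (possibly with missingness),
#'   genoComplete, phenotypes, truth, freq.
#' @export
simulateDataset <- function(config, missing = FALSE, outPrefix = NULL) {
  pop <- simulatePopulation(config)
  gd <- dropGenotypes(pop$pedigree, config)
  sv <- simulateSurvival(gd$geno, pop$cages, pop$pedigree, config)
  geno <- if (missing) injectMissing(gd$geno, config = config) else gd$geno
  res <- list(pedigree = pop$pedigree, cages = pop$cages, geno = geno,
              genoComplete = gd$geno, phenotypes = sv$phenotypes,
              truth = sv$truth, freq = gd$freq)
  if (!is.null(outPrefix)) {
    writePlinkText(geno, paste0(outPrefix, ".ped"), paste0(outPrefix, ".map"),
                   pedigree = pop$pedigree)
    mem <- cageMembers(pop$cages)
    rec <- pedRecords(pop$pedigree)
    k <- match(mem$id, rec$id)
    s <- survivalDays(sv$phenotypes)
    utils::write.csv(data.frame(
      id = mem$id, sire = rec$sire[k], dam = rec$dam[k], cage = mem$cage,
      location = mem$location,
      survival_day = s$survivalDay[match(mem$id, s$id)],
      censored = s$censored[match(mem$id, s$id)]),
      paste0(outPrefix, "_pheno.csv"), row.names = FALSE, quote = FALSE)
    tr <- if (is.null(config$qtl)) data.frame() else config$qtl
    utils::write.table(tr, paste0(outPrefix, "_truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  res
}
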