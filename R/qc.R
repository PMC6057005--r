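.newQcReport <- function() {
  list(snps_removed = c(missingness = 0L, maf = 0L, hwe = 0L, mendel = 0L),
       individuals_removed = c(missingness = 0L, mendel = 0L),
       entries_set_missing = 0L, entries_imputed = 0L,
       filter_order = character())
}

#' Remove SNPs by missingness and MAF
#'
#' Drops SNPs with missing fraction strictly above \code{missThr} or minor
#' allele frequency strictly below \code{mafThr} (computed on non-missing
#' calls), the thresholds of the layer-study genotype QC.
#'
#' @param geno pre-imputation \linkS4class{GenotypeMatrix}.
#' @param missThr,mafThr thresholds (strict inequalities).
#' @param report a QC report list to update (optional).
#' @return list \code{geno}, \code{report}.
#' @export
filterMarkers <- function(geno, missThr = 0.30, mafThr = 0.005,
                          report = .newQcReport()) {
  d <- dosages(geno)
  missFrac <- colMeans(is.na(d))
  maf <- mafs(geno)
  dropMiss <- missFrac > missThr
  dropMaf <- !dropMiss & (is.nan(maf) | maf < mafThr)
  keep <- !(dropMiss | dropMaf)
  if (!any(keep)) stop("all SNPs removed by marker filters: empty panel")
  report$snps_removed["missingness"] <- report$snps_removed["missingness"] +
    sum(dropMiss)
  report$snps_removed["maf"] <- report$snps_removed["maf"] + sum(dropMaf)
  report$filter_order <- c(report$filter_order, "marker_missingness_maf")
  out <- GenotypeMatrix(d[, keep, drop = FALSE],
                        map = new("SnpMap", map = snpMap(geno)[keep, ]))
  list(geno = out, report = report)
}

#' Remove individuals by genotype missingness
#'
#' Drops individuals whose missing fraction exceeds \code{missThr}
#' (strictly).
#'
#' @inheritParams filterMarkers
#' @export
filterIndividuals <- function(geno, missThr = 0.10, report = .newQcReport()) {
  d <- dosages(geno)
  missFrac <- rowMeans(is.na(d))
  keep <- missFrac <= missThr
  if (!any(keep)) stop("all individuals removed: empty panel")
  report$individuals_removed["missingness"] <-
    report$individuals_removed["missingness"] + sum(!keep)
  report$filter_order <- c(report$filter_order, "individual_missingness")
  out <- GenotypeMatrix(d[keep, , drop = FALSE], map = geno@map)
  list(geno = out, report = report)
}

#' Hardy-Weinberg equilibrium filter on the parental population
#'
#' One-degree-of-freedom chi-square goodness of fit of parental genotype
#' counts (n0, n1, n2) against Hardy-Weinberg proportions; SNPs with
#' p strictly below \code{pThr} are removed from the full dataset.
#' Monomorphic SNPs give chi-square 0 and are kept here (the MAF filter
#' owns that case); SNPs without parental calls are skipped with a warning.
#'
#' @param geno \linkS4class{GenotypeMatrix} (full dataset).
#' @param parentIds character ids of the parental individuals present in
#'   \code{geno}.
#' @param pThr removal threshold (strict).
#' @param report QC report list.
#' @return list \code{geno}, \code{report}, \code{pValues} (named, NA for
#'   skipped SNPs).
#' @export
hweFilter <- function(geno, parentIds, pThr = 1e-5, report = .newQcReport()) {
  d <- dosages(geno)
  pd <- d[rownames(d) %in% parentIds, , drop = FALSE]
  n0 <- colSums(pd == 0, na.rm = TRUE)
  n1 <- colSums(pd == 1, na.rm = TRUE)
  n2 <- colSums(pd == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  if (any(n == 0))
    warning(sprintf("%d SNP(s) without parental calls skipped by HWE filter",
                    sum(n == 0)))
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chi2 <- ifelse(n == 0 | p == 0 | p == 1, 0,
                 (n0 - e0)^2 / pmax(e0, .Machine$double.xmin) +
                 (n1 - e1)^2 / pmax(e1, .Machine$double.xmin) +
                 (n2 - e2)^2 / pmax(e2, .Machine$double.xmin))
  pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  pv[n == 0] <- NA
  drop <- !is.na(pv) & pv < pThr
  report$snps_removed["hwe"] <- report$snps_removed["hwe"] + sum(drop)
  report$filter_order <- c(report$filter_order, "hwe_parents")
  out <- GenotypeMatrix(d[, !drop, drop = FALSE],
                        map = new("SnpMap", map = snpMap(geno)[!drop, ]))
  list(geno = out, report = report,
       pValues = stats::setNames(pv, colnames(d)))
}

# Mendelian inconsistency count per entry: offspring vs available parents.
# Returns a logical matrix (offspring x SNPs) marking inconsistent calls.
.mendelErrors <- function(d, rec) {
  ids <- rownames(d)
  si <- match(rec$sire[match(ids, rec$id)], ids)
  di <- match(rec$dam[match(ids, rec$id)], ids)
  err <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
  hasS <- !is.na(si); hasD <- !is.na(di)
  o <- d
  if (any(hasS)) {
    s <- d[si[hasS], , drop = FALSE]
    oo <- o[hasS, , drop = FALSE]
    # opposite homozygotes with one parent
    e <- (oo == 0 & s == 2) | (oo == 2 & s == 0)
    e[is.na(e)] <- FALSE
    err[hasS, ] <- err[hasS, ] | e
  }
  if (any(hasD)) {
    dm <- d[di[hasD], , drop = FALSE]
    oo <- o[hasD, , drop = FALSE]
    e <- (oo == 0 & dm == 2) | (oo == 2 & dm == 0)
    e[is.na(e)] <- FALSE
    err[hasD, ] <- err[hasD, ] | e
  }
  both <- hasS & hasD
  if (any(both)) {
    s <- d[si[both], , drop = FALSE]
    dm <- d[di[both], , drop = FALSE]
    oo <- o[both, , drop = FALSE]
    # trio impossibilities not caught pairwise: both parents homozygous
    e <- (s == 0 & dm == 0 & oo != 0) | (s == 2 & dm == 2 & oo != 2) |
         (((s == 0 & dm == 2) | (s == 2 & dm == 0)) & oo != 1)
    e[is.na(e)] <- FALSE
    err[both, ] <- err[both, ] | e
  }
  err
}

#' Mendelian-error filter
#'
#' Counts Mendelian inconsistencies between each offspring and its available
#' parent genotypes (opposite homozygotes; trio-impossible transmissions).
#' SNPs with more than \code{snpMax} errors and individuals with more than
#' \code{indMax} errors are removed; remaining inconsistent offspring calls
#' are set to missing.
#'
#' @param geno \linkS4class{GenotypeMatrix}.
#' @param pedigree \linkS4class{Pedigree}.
#' @param snpMax,indMax tolerated error counts (strict "more than").
#' @param report QC report list.
#' @return list \code{geno}, \code{report}.
#' @export
mendelFilter <- function(geno, pedigree, snpMax = 1L, indMax = 5L,
                         report = .newQcReport()) {
  d <- dosages(geno)
  rec <- pedRecords(pedigree)
  err <- .mendelErrors(d, rec)
  dropSnp <- colSums(err) > snpMax
  dropInd <- rowSums(err) > indMax
  report$snps_removed["mendel"] <- report$snps_removed["mendel"] + sum(dropSnp)
  report$individuals_removed["mendel"] <-
    report$individuals_removed["mendel"] + sum(dropInd)
  d2 <- d[!dropInd, !dropSnp, drop = FALSE]
  left <- err[!dropInd, !dropSnp, drop = FALSE]
  d2[left] <- NA
  report$entries_set_missing <- report$entries_set_missing + sum(left)
  report$filter_order <- c(report$filter_order, "mendel")
  out <- GenotypeMatrix(d2, map = new("SnpMap",
                                      map = snpMap(geno)[!dropSnp, ]))
  list(geno = out, report = report)
}

#' Parental-mean imputation of missing genotypes
#'
#' A missing dosage is replaced by the average of the sire's allele count
#' and the mean allele count of the sire's mates (dams with at least one
#' offspring by that sire in the pedigree), divided by two:
#' (sire + mean(mates)) / 2. When the sire's or all mates' genotypes are
#' unavailable the line mean (2 x counted-allele frequency among non-missing
#' calls) is used. Observed genotypes are never changed; the output has no
#' missing values and fractional dosages are allowed.
#'
#' @param geno \linkS4class{GenotypeMatrix} after the QC filters.
#' @param pedigree \linkS4class{Pedigree}.
#' @param report QC report list.
#' @return list \code{geno} (imputed), \code{report}.
#' @export
imputeParentalMean <- function(geno, pedigree, report = .newQcReport()) {
  d <- dosages(geno)
  d0 <- d                                        # observed calls only
  rec <- pedRecords(pedigree)
  lineMean <- colMeans(d0, na.rm = TRUE)         # = 2p
  lineMean[is.nan(lineMean)] <- 1                # empty SNP: frequency 0.5
  nmiss <- sum(is.na(d))

  sires <- unique(rec$sire[!is.na(rec$sire)])
  mates <- lapply(stats::setNames(sires, sires), function(s)
    unique(rec$dam[!is.na(rec$sire) & rec$sire == s & !is.na(rec$dam)]))

  ids <- rownames(d)
  mySire <- rec$sire[match(ids, rec$id)]
  for (i in which(rowSums(is.na(d)) > 0)) {
    j <- which(is.na(d[i, ]))
    s <- mySire[i]
    fill <- lineMean[j]
    if (!is.na(s) && s %in% ids) {
      sg <- d0[s, j]
      mt <- mates[[s]]
      mt <- mt[mt %in% ids]
      mg <- if (length(mt)) colMeans(d0[mt, j, drop = FALSE], na.rm = TRUE)
            else rep(NaN, length(j))
      ok <- !is.na(sg) & !is.nan(mg)
      fill[ok] <- (sg[ok] + mg[ok]) / 2
    }
    d[i, j] <- fill
  }
  report$entries_imputed <- report$entries_imputed + nmiss
  list(geno = GenotypeMatrix(d, map = geno@map, imputed = TRUE),
       report = report)
}

#' Run the full genotype QC pipeline
#'
#' Fixed filter order: marker missingness/MAF, individual missingness, HWE
#' in the parental population, Mendelian checks, then parental-mean
#' imputation. The report records the order and all removal counts.
#'
#' @param geno \linkS4class{GenotypeMatrix} (parents and offspring).
#' @param pedigree \linkS4class{Pedigree}.
#' @param missThrSnp,mafThr,missThrInd,hwePThr,mendelSnpMax,mendelIndMax
#'   thresholds, see the individual filters.
#' @param impute run \code{\link{imputeParentalMean}} at the end.
#' @return list \code{geno}, \code{report}.
#' @export
runQc <- function(geno, pedigree, missThrSnp = 0.30, mafThr = 0.005,
                  missThrInd = 0.10, hwePThr = 1e-5,
                  mendelSnpMax = 1L, mendelIndMax = 5L, impute = TRUE) {
  rec <- pedRecords(pedigree)
  parents <- unique(c(rec$sire, rec$dam))
  parents <- parents[!is.na(parents)]
  st <- filterMarkers(geno, missThrSnp, mafThr)
  st <- filterIndividuals(st$geno, missThrInd, report = st$report)
  st2 <- hweFilter(st$geno, parents, hwePThr, report = st$report)
  st3 <- mendelFilter(st2$geno, pedigree, mendelSnpMax, mendelIndMax,
                      report = st2$report)
  if (impute) st3 <- imputeParentalMean(st3$geno, pedigree, report = st3$report)
  st3
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular (recursive) method over individuals sorted by generation:
#' a_ii = 1 + a_sd / 2 and a_ij = (a_js + a_jd) / 2, with unknown parents
#' contributing 0. At most \code{maxGenerations} most recent generations are
#' used (ancestors beyond the window are treated as founders).
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param maxGenerations pedigree depth retained.
#' @return dense symmetric matrix with id dimnames (class matrix); founder
#'   diagonal 1, positive semi-definite.
#' @export
buildA <- function(pedigree, maxGenerations = 5L) {
  rec <- pedRecords(pedigree)
  gmax <- max(rec$generation)
  keepGen <- rec$generation > gmax - maxGenerations
  rec <- rec[keepGen, , drop = FALSE]
  ord <- order(rec$generation)
  rec <- rec[ord, , drop = FALSE]
  n <- nrow(rec)
  si <- match(rec$sire, rec$id); di <- match(rec$dam, rec$id)
  A <- matrix(0, n, n, dimnames = list(rec$id, rec$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with Quaas' inbreeding adjustment: the Mendelian
#' sampling variance of individual i is d_i = 0.5 - 0.25 (F_s + F_d) with
#' both parents known, 0.75 - 0.25 F_p with one, and 1 for founders.
#' Inbreeding coefficients come from \code{\link{buildA}} unless supplied.
#'
#' @param pedigree a \linkS4class{Pedigree}.
#' @param inbreeding optional named vector of inbreeding coefficients F;
#'   \code{"zero"} asserts a non-inbred pedigree (skips the dense build).
#' @return sparse symmetric \code{Matrix} (dsCMatrix) with id dimnames.
#' @export
buildAinv <- function(pedigree, inbreeding = NULL) {
  rec <- pedRecords(pedigree)
  ord <- order(rec$generation)
  rec <- rec[ord, , drop = FALSE]
  n <- nrow(rec)
  si <- match(rec$sire, rec$id); di <- match(rec$dam, rec$id)
  if (identical(inbreeding, "zero")) {
    f <- numeric(n)
  } else if (is.null(inbreeding)) {
    f <- diag(buildA(pedigree, maxGenerations = max(rec$generation) + 1L)) - 1
    f <- f[rec$id]
  } else f <- inbreeding[rec$id]

  fs <- ifelse(is.na(si), 0, f[si]); fd <- ifelse(is.na(di), 0, f[di])
  dI <- ifelse(!is.na(si) & !is.na(di), 0.5 - 0.25 * (fs + fd),
        ifelse(!is.na(si) | !is.na(di), 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / dI

  hs <- which(!is.na(si)); hd <- which(!is.na(di))
  both <- which(!is.na(si) & !is.na(di))
  ii <- c(seq_len(n),
          hs, si[hs], si[hs],
          hd, di[hd], di[hd],
          si[both], di[both])
  jj <- c(seq_len(n),
          si[hs], hs, si[hs],
          di[hd], hd, di[hd],
          di[both], si[both])
  xx <- c(alpha,
          -0.5 * alpha[hs], -0.5 * alpha[hs], 0.25 * alpha[hs],
          -0.5 * alpha[hd], -0.5 * alpha[hd], 0.25 * alpha[hd],
          0.25 * alpha[both], 0.25 * alpha[both])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(rec$id, rec$id))
  methods::as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
}
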