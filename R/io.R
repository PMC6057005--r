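#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses whitespace-delimited PLINK text files into a
#' \linkS4class{GenotypeMatrix}, a \linkS4class{SnpMap} and a pedigree
#' fragment taken from the family columns of the .ped file. Dosages count
#' copies of the counted allele, which is fixed per SNP as the first
#' non-missing allele symbol encountered; "0 0" pairs become missing.
#'
#' @param pedPath path to the .ped file (6 leading columns FID, IID, PAT,
#'   MAT, SEX, PHENO, then two allele columns per SNP).
#' @param mapPath path to the .map file (4 columns: chrom, snp id, genetic
#'   distance, bp position).
#' @return list with elements \code{geno} (\linkS4class{GenotypeMatrix}),
#'   \code{map} (\linkS4class{SnpMap}) and \code{pedigree}
#'   (\linkS4class{Pedigree} fragment from PAT/MAT columns).
#' @export
readPlinkText <- function(pedPath, mapPath) {
  stopifnot(file.exists(pedPath), file.exists(mapPath))
  mp <- utils::read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) != 4)
    stop(".map file must have 4 columns (chrom, snp, cM, pos)")
  nsnp <- nrow(mp)

  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  want <- 6L + 2L * nsnp
  if (any(len != want))
    stop(sprintf(".ped parse error: line %d has %d fields, expected %d",
                 which(len != want)[1], len[len != want][1], want))
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  iid <- tok[, 2]
  if (anyDuplicated(iid)) stop("duplicate individual id in .ped")

  al <- tok[, -(1:6), drop = FALSE]
  bad <- !(al %in% c("A", "C", "G", "T", "1", "2", "0"))
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf(".ped parse error: allele symbol '%s' (line %d)",
                 al[k], (k - 1L) %% nrow(al) + 1L))
  }
  a1 <- al[, 2 * seq_len(nsnp) - 1, drop = FALSE]
  a2 <- al[, 2 * seq_len(nsnp), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  miss <- is.na(a1) | is.na(a2)   # half-missing treated as missing call
  a1[miss] <- NA; a2[miss] <- NA

  counted <- apply(a1, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else "A"
  })
  # second pass for SNPs whose first a1 exists but scan both columns to fix
  # the counted allele as the first allele observed in reading order
  for (j in seq_len(nsnp)) {
    pair <- as.vector(rbind(a1[, j], a2[, j]))
    pair <- pair[!is.na(pair)]
    counted[j] <- if (length(pair)) pair[1] else "A"
  }
  dose <- (a1 == rep(counted, each = nrow(a1))) +
          (a2 == rep(counted, each = nrow(a2)))
  dose <- matrix(as.numeric(dose), nrow = nrow(a1),
                 dimnames = list(iid, mp[, 2]))

  map <- SnpMap(snp = mp[, 2], chrom = mp[, 1], pos = mp[, 4], counted = counted)
  ped <- Pedigree(id = iid, sire = tok[, 3], dam = tok[, 4])
  list(geno = GenotypeMatrix(dose, map = map, imputed = FALSE),
       map = map, pedigree = ped)
}

#' Write PLINK text genotypes
#'
#' Inverse of \code{\link{readPlinkText}} for integer (non-imputed) dosage
#' matrices. Counted-allele homozygotes are written as two copies of the
#' counted allele; the other allele symbol is taken from \code{other}.
#'
#' @param geno a \linkS4class{GenotypeMatrix} with integer entries.
#' @param pedigree optional \linkS4class{Pedigree} supplying PAT/MAT columns.
#' @param pedPath,mapPath output paths.
#' @param other allele symbol used for the non-counted allele.
#' @return invisibly, the two paths.
#' @export
writePlinkText <- function(geno, pedPath, mapPath, pedigree = NULL,
                           other = "G") {
  d <- dosages(geno)
  stopifnot(all(is.na(d) | d == round(d)))
  m <- snpMap(geno)
  oth <- ifelse(m$counted == other, "A", other)
  utils::write.table(
    data.frame(m$chrom, m$snp, 0, m$pos),
    mapPath, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")

  ids <- rownames(d)
  sire <- dam <- rep("0", length(ids))
  if (!is.null(pedigree)) {
    rec <- pedRecords(pedigree)
    k <- match(ids, rec$id)
    sire <- ifelse(is.na(rec$sire[k]), "0", rec$sire[k])
    dam <- ifelse(is.na(rec$dam[k]), "0", rec$dam[k])
  }
  cntM <- matrix(rep(m$counted, each = nrow(d)), nrow = nrow(d))
  othM <- matrix(rep(oth, each = nrow(d)), nrow = nrow(d))
  A1 <- ifelse(is.na(d), "0", ifelse(d >= 1, cntM, othM))
  A2 <- ifelse(is.na(d), "0", ifelse(d == 2, cntM, othM))
  inter <- matrix("", nrow(d), 2 * ncol(d))
  inter[, seq(1, 2 * ncol(d), 2)] <- A1
  inter[, seq(2, 2 * ncol(d), 2)] <- A2
  lead <- cbind("FAM", ids, sire, dam, "0", "-9")
  writeLines(apply(cbind(lead, inter), 1, paste, collapse = " "), pedPath)
  invisible(c(pedPath, mapPath))
}

#' Read the phenotype/cage CSV
#'
#' Expects a header with columns id, sire, dam, cage, location, survival_day,
#' censored. Validates survival days against the censoring cap and flags
#' cages violating the design rules (wrong size or multiple sires), as cages
#' with mistakes in their composition are removed from analysis.
#'
#' @param csvPath path to the CSV file.
#' @param censorDay,nMonths recording-period length and monthly record count.
#' @return list with \code{phenotypes} (\linkS4class{PhenotypeSet}),
#'   \code{cages} (\linkS4class{CageLayout}), \code{pedigree}
#'   (\linkS4class{Pedigree} fragment) and \code{flaggedCages} (character
#'   vector of cage ids violating the size or single-sire rule).
#' @export
readPhenotypes <- function(csvPath, censorDay = 402, nMonths = 13L) {
  df <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "cage", "location", "survival_day", "censored")
  if (!all(need %in% names(df)))
    stop(sprintf("phenotype CSV must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate id in phenotype CSV: %s",
                 df$id[duplicated(df$id)][1]))
  if (any(df$survival_day < 1 | df$survival_day > censorDay))
    stop(sprintf("survival_day outside [1, %d] for id %s", censorDay,
                 df$id[df$survival_day < 1 | df$survival_day > censorDay][1]))
  cens <- df$censored
  if (is.character(cens)) cens <- tolower(cens) %in% c("true", "t", "1", "yes")
  cens <- as.logical(cens)

  phen <- PhenotypeSet(df$id, df$survival_day, cens, censorDay = censorDay,
                       nMonths = nMonths)
  loc <- df[!duplicated(df$cage), c("cage", "location")]
  cages <- CageLayout(df$id, df$cage, location = loc)
  flagged <- checkCages(cages, Pedigree(df$id, df$sire, df$dam))
  list(phenotypes = phen, cages = cages,
       pedigree = Pedigree(df$id, df$sire, df$dam), flaggedCages = flagged)
}

#' Flag cages violating the design composition rules
#'
#' A valid cage holds exactly \code{cageSize} members that all descend from
#' one sire (paternal half- or full-sibs). Cages failing either rule are
#' returned for removal, mirroring the exclusion of cages with mistakes in
#' their composition.
#'
#' @param cages a \linkS4class{CageLayout}.
#' @param pedigree a \linkS4class{Pedigree} covering the members.
#' @return character vector of offending cage ids.
#' @export
checkCages <- function(cages, pedigree) {
  m <- cages@members
  rec <- pedRecords(pedigree)
  sire <- rec$sire[match(m$id, rec$id)]
  bad <- vapply(split(seq_len(nrow(m)), m$cage), function(ix) {
    s <- unique(sire[ix])
    length(ix) != cages@cageSize || length(s[!is.na(s)]) > 1
  }, logical(1))
  names(bad)[bad]
}

#' Derive monthly 0/1 survival records
#'
#' The recording period of \code{censorDay} days is split into
#' \code{nMonths} equal blocks with boundary day \code{round(censorDay * m /
#' nMonths)} for month m. The record for month m is 1 when the individual
#' was still alive at that boundary (survival day >= boundary), 0 afterwards;
#' dead individuals keep 0 records for all remaining months so every
#' individual contributes exactly \code{nMonths} records.
#'
#' @param phenotypes a \linkS4class{PhenotypeSet}.
#' @return integer matrix (individuals x months) with rownames = ids and an
#'   attribute \code{"boundaries"} giving the boundary days.
#' @export
monthlyRecords <- function(phenotypes) {
  s <- survivalDays(phenotypes)
  m <- seq_len(phenotypes@nMonths)
  bound <- round(phenotypes@censorDay * m / phenotypes@nMonths)
  rec <- outer(s$survivalDay, bound, ">=") + 0L
  dimnames(rec) <- list(s$id, paste0("m", m))
  attr(rec, "boundaries") <- bound
  rec
}

.scanCols <- c("snp_id", "chrom", "pos", "maf",
               "beta_D", "se_D", "stat_D", "p_D", "p_D_gc", "q_D",
               "beta_I", "se_I", "stat_I", "p_I", "p_I_gc", "q_I", "model")

#' Write / read a scan result TSV
#'
#' Deterministic column order; full double precision so a round trip
#' reproduces values to 1e-12.
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param path output (input) path.
#' @return \code{writeScanResults}: invisibly the path;
#'   \code{readScanResults}: a \linkS4class{ScanResult}.
#' @export
writeScanResults <- function(scan, path) {
  tab <- scanTable(scan)
  for (cl in .scanCols) if (!cl %in% names(tab)) tab[[cl]] <- NA
  tab <- tab[, .scanCols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(.scanCols, collapse = "\t"), con)
  if (nrow(tab)) {
    fmt <- function(x) if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
    body <- do.call(paste, c(lapply(tab, fmt), sep = "\t"))
    body <- gsub("\\bNA\\b", "NA", body)
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname writeScanResults
#' @export
readScanResults <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  model <- if (nrow(tab)) tab$model[1] else NA_character_
  new("ScanResult", table = tab, model = model, gc = list())
}
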