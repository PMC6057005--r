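#' @import methods
#' @importFrom Matrix Cholesky Diagonal sparseMatrix crossprod t solve
#'   forceSymmetric bdiag determinant update colSums rowSums
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Pedigree of sire/dam/offspring records
#'
#' Holds one record per individual with its sire, dam and generation index.
#' Unknown parents are coded \code{NA}; individuals with both parents unknown
#' are founders. Used to build the additive relationship matrix and to check
#' Mendelian consistency of genotypes.
#'
#' @slot records data.frame with columns \code{id}, \code{sire}, \code{dam}
#'   (character, \code{NA} for unknown) and \code{generation} (integer >= 0).
#' @export
setClass("Pedigree", representation(records = "data.frame"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  need <- c("id", "sire", "dam", "generation")
  if (!all(need %in% names(rec)))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id)) return("duplicate individual ids")
  if (any(rec$generation < 0, na.rm = TRUE)) return("negative generation index")
  idx <- match(rec$sire, rec$id)
  ok <- is.na(rec$sire) | is.na(idx) | rec$generation > rec$generation[idx]
  idxd <- match(rec$dam, rec$id)
  okd <- is.na(rec$dam) | is.na(idxd) | rec$generation > rec$generation[idxd]
  if (!all(ok & okd))
    return("offspring generation index must exceed that of known parents")
  if (any(!is.na(rec$sire) & rec$sire == rec$id) ||
      any(!is.na(rec$dam) & rec$dam == rec$id))
    return("an individual cannot be its own parent")
  TRUE
})

#' Construct a Pedigree
#'
#' @param id character vector of individual ids.
#' @param sire,dam character vectors of parent ids; \code{NA}, \code{""} or
#'   \code{"0"} mean unknown.
#' @param generation optional integer generation index; derived from parental
#'   depth when missing.
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(id, sire = NA, dam = NA, generation = NULL) {
  id <- as.character(id)
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("", "0", "NA")] <- NA_character_
    rep_len(x, length(id))
  }
  sire <- clean(sire); dam <- clean(dam)
  if (is.null(generation)) {
    generation <- rep(NA_integer_, length(id))
    known <- is.na(sire) & is.na(dam)
    generation[known] <- 0L
    # iterate: generation = 1 + max(parent generations), parents absent from
    # the records count as founders (generation -1 here, i.e. contribute 0)
    for (it in seq_len(length(id) + 1L)) {
      if (!anyNA(generation)) break
      gs <- generation[match(sire, id)]; gd <- generation[match(dam, id)]
      gs[is.na(sire) | is.na(match(sire, id))] <- -1L
      gd[is.na(dam) | is.na(match(dam, id))] <- -1L
      ready <- is.na(generation) & !is.na(gs) & !is.na(gd)
      if (!any(ready)) break
      generation[ready] <- pmax(gs[ready], gd[ready]) + 1L
    }
    if (anyNA(generation)) stop("pedigree contains a cycle")
  }
  new("Pedigree", records = data.frame(
    id = id, sire = sire, dam = dam,
    generation = as.integer(generation), stringsAsFactors = FALSE))
}

#' @describeIn Pedigree number of individuals
#' @param x,object a \code{Pedigree}
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@records))

#' Accessor for pedigree records
#' @param object a \linkS4class{Pedigree}
#' @return data.frame of records.
#' @export
setGeneric("pedRecords", function(object) standardGeneric("pedRecords"))

#' @rdname pedRecords
#' @export
setMethod("pedRecords", "Pedigree", function(object) object@records)

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  cat(sprintf("Pedigree: %d individuals, %d founders, generations 0..%d\n",
              nrow(rec), sum(is.na(rec$sire) & is.na(rec$dam)),
              max(rec$generation)))
})

#' Marker map for a SNP panel
#'
#' @slot map data.frame with columns \code{snp} (unique id), \code{chrom},
#'   \code{pos} (1-based bp) and \code{counted} (the allele whose copies the
#'   dosage counts).
#' @export
setClass("SnpMap", representation(map = "data.frame"))

setValidity("SnpMap", function(object) {
  m <- object@map
  need <- c("snp", "chrom", "pos", "counted")
  if (!all(need %in% names(m)))
    return(sprintf("map must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(m$snp)) return("snp ids must be unique")
  if (any(m$pos < 0)) return("positions must be >= 0")
  TRUE
})

#' @rdname SnpMap-class
#' @param snp,chrom,pos,counted map columns (recycled to common length).
#' @return A \linkS4class{SnpMap}.
#' @export
SnpMap <- function(snp, chrom = "1", pos = seq_along(snp), counted = "A") {
  new("SnpMap", map = data.frame(
    snp = as.character(snp), chrom = as.character(chrom),
    pos = as.integer(pos), counted = as.character(counted),
    stringsAsFactors = FALSE))
}

#' Accessor for SNP map table
#' @param object a \linkS4class{SnpMap} or \linkS4class{GenotypeMatrix}
#' @return data.frame of map columns.
#' @export
setGeneric("snpMap", function(object) standardGeneric("snpMap"))

#' @rdname snpMap
#' @export
setMethod("snpMap", "SnpMap", function(object) object@map)

setMethod("show", "SnpMap", function(object) {
  cat(sprintf("SnpMap: %d SNPs on %d chromosome(s)\n",
              nrow(object@map), length(unique(object@map$chrom))))
})

#' Genotype dosage matrix
#'
#' Individuals by SNPs matrix of counted-allele dosages. Before imputation
#' entries are integer counts in \{0, 1, 2\} or \code{NA}; after parental-mean
#' imputation entries may be fractional dosages in [0, 2] and the
#' \code{imputed} flag is set.
#'
#' @slot dosage numeric matrix with rownames = individual ids, colnames = snp
#'   ids aligned to the map.
#' @slot map a \linkS4class{SnpMap}.
#' @slot imputed logical; \code{TRUE} once missing entries have been filled.
#' @export
setClass("GenotypeMatrix",
         representation(dosage = "matrix", map = "SnpMap", imputed = "logical"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  if (!identical(colnames(d), snpMap(object@map)$snp))
    return("dosage colnames must match map snp ids")
  if (is.null(rownames(d))) return("dosage must have individual ids as rownames")
  v <- d[!is.na(d)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    return("dosages must lie in [0, 2]")
  if (!object@imputed && length(v) && any(v != round(v)))
    return("pre-imputation entries must be integer counts or NA")
  if (object@imputed && anyNA(d))
    return("imputed matrix must not contain missing entries")
  TRUE
})

#' @rdname GenotypeMatrix-class
#' @param dosage numeric matrix (individuals x SNPs).
#' @param map a \linkS4class{SnpMap} (default: generic map from colnames).
#' @param imputed logical.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, map = NULL, imputed = FALSE) {
  if (is.null(map)) map <- SnpMap(colnames(dosage))
  new("GenotypeMatrix", dosage = dosage, map = map, imputed = imputed)
}

#' Accessor for the dosage matrix
#' @param object a \linkS4class{GenotypeMatrix}
#' @return numeric matrix of dosages.
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeMatrix", function(object) object@dosage)

#' @rdname snpMap
#' @export
setMethod("snpMap", "GenotypeMatrix", function(object) object@map@map)

#' @describeIn GenotypeMatrix dimensions (individuals, SNPs)
#' @param x,object a \code{GenotypeMatrix}
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosage
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%s; %.2f%% missing)\n",
              nrow(d), ncol(d),
              if (object@imputed) "imputed dosages" else "integer counts",
              100 * mean(is.na(d))))
})

#' Minor allele frequencies
#'
#' MAF per SNP from non-missing dosages: \code{min(f, 1 - f)} where \code{f}
#' is the counted-allele frequency.
#' @param object a \linkS4class{GenotypeMatrix}
#' @return named numeric vector of MAF (NaN for SNPs with no calls).
#' @export
setGeneric("mafs", function(object) standardGeneric("mafs"))

#' @rdname mafs
#' @export
setMethod("mafs", "GenotypeMatrix", function(object) {
  f <- colMeans(object@dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
})

#' Cage layout: group membership and location factor
#'
#' Maps each individual to exactly one cage and each cage to a location label
#' (the wing-row-level combination of the housing design). Cage mates share a
#' sire in the intended design; \code{\link{checkCages}} flags violations.
#'
#' @slot members data.frame with columns \code{id}, \code{cage} (character).
#' @slot locations data.frame with columns \code{cage}, \code{location}.
#' @slot cageSize intended number of members per cage at start (default 5).
#' @export
setClass("CageLayout",
         representation(members = "data.frame", locations = "data.frame",
                        cageSize = "integer"))

setValidity("CageLayout", function(object) {
  if (anyDuplicated(object@members$id))
    return("each individual must belong to exactly one cage")
  if (!all(object@members$cage %in% object@locations$cage))
    return("every cage must have a location")
  if (anyDuplicated(object@locations$cage))
    return("duplicate cage in locations table")
  TRUE
})

#' @rdname CageLayout-class
#' @param id,cage character vectors (one row per individual).
#' @param location named or positional character vector per unique cage, or a
#'   data.frame with columns cage, location.
#' @param cageSize intended members per cage.
#' @return A \linkS4class{CageLayout}.
#' @export
CageLayout <- function(id, cage, location, cageSize = 5L) {
  members <- data.frame(id = as.character(id), cage = as.character(cage),
                        stringsAsFactors = FALSE)
  if (is.data.frame(location)) {
    locations <- data.frame(cage = as.character(location$cage),
                            location = as.character(location$location),
                            stringsAsFactors = FALSE)
  } else {
    u <- unique(members$cage)
    loc <- if (!is.null(names(location))) location[u] else rep_len(location, length(u))
    locations <- data.frame(cage = u, location = as.character(loc),
                            stringsAsFactors = FALSE)
  }
  new("CageLayout", members = members, locations = locations,
      cageSize = as.integer(cageSize))
}

#' Accessors for cage layout
#' @param object a \linkS4class{CageLayout}
#' @return \code{cageMembers}: data.frame id, cage, location (one row per
#'   individual); \code{cageOf}: named character vector cage per individual.
#' @export
setGeneric("cageMembers", function(object) standardGeneric("cageMembers"))

#' @rdname cageMembers
#' @export
setMethod("cageMembers", "CageLayout", function(object) {
  m <- object@members
  m$location <- object@locations$location[match(m$cage, object@locations$cage)]
  m
})

#' @rdname cageMembers
#' @export
setGeneric("cageOf", function(object) standardGeneric("cageOf"))

#' @rdname cageMembers
#' @export
setMethod("cageOf", "CageLayout", function(object) {
  structure(object@members$cage, names = object@members$id)
})

setMethod("show", "CageLayout", function(object) {
  cat(sprintf("CageLayout: %d individuals in %d cages (size %d), %d location(s)\n",
              nrow(object@members), nrow(object@locations), object@cageSize,
              length(unique(object@locations$location))))
})

#' Survival phenotypes with derived monthly binary records
#'
#' Per-individual survival day on a study of \code{censorDay} days; animals
#' alive at the end of the study are censored and assigned
#' \code{survivalDay == censorDay}. Monthly 0/1 records are derived with
#' \code{\link{monthlyRecords}}.
#'
#' @slot survival data.frame with columns \code{id}, \code{survivalDay}
#'   (integer in [1, censorDay]) and \code{censored} (logical).
#' @slot censorDay length of the recording period in days (402 in the layer
#'   study design).
#' @slot nMonths number of monthly binary records per individual (13).
#' @export
setClass("PhenotypeSet",
         representation(survival = "data.frame", censorDay = "numeric",
                        nMonths = "integer"))

setValidity("PhenotypeSet", function(object) {
  s <- object@survival
  if (!all(c("id", "survivalDay", "censored") %in% names(s)))
    return("survival needs columns id, survivalDay, censored")
  if (anyDuplicated(s$id)) return("duplicate individual id")
  if (any(s$survivalDay < 1 | s$survivalDay > object@censorDay))
    return(sprintf("survivalDay must lie in [1, %d]", object@censorDay))
  if (any(s$censored & s$survivalDay != object@censorDay))
    return("censored individuals must have survivalDay == censorDay")
  TRUE
})

#' @rdname PhenotypeSet-class
#' @param id character ids.
#' @param survivalDay integer days survived (capped at \code{censorDay}).
#' @param censored logical; alive at the end of the recording period.
#' @param censorDay,nMonths study length in days and number of monthly records.
#' @return A \linkS4class{PhenotypeSet}.
#' @export
PhenotypeSet <- function(id, survivalDay, censored = survivalDay >= censorDay,
                         censorDay = 402, nMonths = 13L) {
  new("PhenotypeSet",
      survival = data.frame(id = as.character(id),
                            survivalDay = as.integer(survivalDay),
                            censored = as.logical(censored),
                            stringsAsFactors = FALSE),
      censorDay = censorDay, nMonths = as.integer(nMonths))
}

#' Accessor for survival records
#' @param object a \linkS4class{PhenotypeSet}
#' @return data.frame id, survivalDay, censored.
#' @export
setGeneric("survivalDays", function(object) standardGeneric("survivalDays"))

#' @rdname survivalDays
#' @export
setMethod("survivalDays", "PhenotypeSet", function(object) object@survival)

#' @describeIn PhenotypeSet number of individuals
#' @param x,object a \code{PhenotypeSet}
#' @export
setMethod("length", "PhenotypeSet", function(x) nrow(x@survival))

setMethod("show", "PhenotypeSet", function(object) {
  s <- object@survival
  cat(sprintf(
    "PhenotypeSet: %d individuals, mean survival %.1f d (censoring at %g d: %.1f%%), %d monthly records each\n",
    nrow(s), mean(s$survivalDay), object@censorDay,
    100 * mean(s$censored), object@nMonths))
})

#' Null mixed-model fit (variance components without SNP effects)
#'
#' @slot model one of "STM", "RMM.t", "GLMM".
#' @slot varcomp named numeric vector of variance components.
#' @slot varcompSE asymptotic standard errors (delta method from the
#'   log-scale observed information), NA where unavailable.
#' @slot fixef named numeric vector of fixed-effect estimates.
#' @slot logLik REML log-likelihood (up to an additive constant).
#' @slot engine internal list holding the covariance factorization reused by
#'   the SNP scan (design matrices, inverse-part Cholesky, residual weights).
#' @slot sigmaP2 phenotypic variance on the model's scale (STM: sum of
#'   components, days^2).
#' @export
setClass("NullModelFit",
         representation(model = "character", varcomp = "numeric",
                        varcompSE = "numeric", fixef = "numeric",
                        logLik = "numeric", engine = "list",
                        sigmaP2 = "numeric"))

setMethod("show", "NullModelFit", function(object) {
  cat(sprintf("NullModelFit [%s]: logLik %.3f\n", object@model, object@logLik))
  vc <- data.frame(estimate = object@varcomp, se = object@varcompSE)
  print(round(vc, 4))
  if (object@model == "STM") {
    th <- totalHeritableParams(object)
    cat(sprintf("  sigmaP2 = %.1f, T2 = %.3f, sigmaA = %.1f days\n",
                object@sigmaP2, th[["T2"]], th[["sigmaA"]]))
  }
})

#' Accessors for null-model fits
#' @param object a \linkS4class{NullModelFit}
#' @return \code{varComp}: named numeric vector of variance components;
#'   \code{fixedEffects}: named numeric vector.
#' @export
setGeneric("varComp", function(object) standardGeneric("varComp"))

#' @rdname varComp
#' @export
setMethod("varComp", "NullModelFit", function(object) object@varcomp)

#' @rdname varComp
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' @rdname varComp
#' @export
setMethod("fixedEffects", "NullModelFit", function(object) object@fixef)

#' Per-SNP scan result
#'
#' One row per SNP with simultaneously fitted direct and indirect effect
#' estimates, Wald statistics and p-values, genomic-control adjusted
#' p-values and q-values (filled by \code{\link{genomicControl}} and
#' \code{\link{estimateQvalues}}).
#'
#' @slot table data.frame with columns snp_id, chrom, pos, maf, beta_D, se_D,
#'   stat_D, p_D, p_D_gc, q_D, beta_I, se_I, stat_I, p_I, p_I_gc, q_I, model.
#' @slot model model tag.
#' @slot gc list with lambda_direct, lambda_indirect, applied (set by
#'   \code{genomicControl}).
#' @export
setClass("ScanResult",
         representation(table = "data.frame", model = "character", gc = "list"))

setMethod("show", "ScanResult", function(object) {
  tab <- object@table
  cat(sprintf("ScanResult [%s]: %d SNPs", object@model, nrow(tab)))
  if (length(object@gc))
    cat(sprintf(" (lambda D=%.3f I=%.3f, GC %s)",
                object@gc$lambda_direct, object@gc$lambda_indirect,
                if (isTRUE(object@gc$applied_direct) ||
                    isTRUE(object@gc$applied_indirect)) "applied" else "not applied"))
  cat("\n")
  if (nrow(tab)) {
    top <- tab[order(tab$p_D), ][seq_len(min(3, nrow(tab))),
                                 c("snp_id", "maf", "beta_D", "se_D", "p_D")]
    cat("  top direct associations:\n")
    print(top, row.names = FALSE, digits = 3)
  }
})

#' Accessor for the scan table
#' @param object a \linkS4class{ScanResult}
#' @return data.frame, one row per SNP.
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))

#' @rdname scanTable
#' @export
setMethod("scanTable", "ScanResult", function(object) object@table)

#' Backwards-elimination result
#'
#' @slot retained data.frame of effects kept in the final joint model:
#'   snp_id, effect ("direct"/"indirect"), maf, major allele frequency p,
#'   alpha_days, se, p, V_days2, pct_sigmaP2, pct_sigmaA2.
#' @slot trace data.frame logging the drop order (step, snp_id, effect, p at
#'   drop time, reason).
#' @slot pThreshold the implied per-test p threshold used.
#' @export
setClass("EliminationResult",
         representation(retained = "data.frame", trace = "data.frame",
                        pThreshold = "numeric"))

setMethod("show", "EliminationResult", function(object) {
  cat(sprintf("EliminationResult: %d effect(s) retained (p threshold %.3g), %d dropped\n",
              nrow(object@retained), object@pThreshold, nrow(object@trace)))
  if (nrow(object@retained))
    print(object@retained[, c("snp_id", "effect", "alpha_days", "se", "p",
                              "V_days2", "pct_sigmaP2", "pct_sigmaA2")],
          row.names = FALSE, digits = 3)
})

#' Accessor for retained effects after elimination
#' @param object an \linkS4class{EliminationResult}
#' @return data.frame of retained effects.
#' @export
setGeneric("retainedEffects", function(object) standardGeneric("retainedEffects"))

#' @rdname retainedEffects
#' @export
setMethod("retainedEffects", "EliminationResult", function(object) object@retained)
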