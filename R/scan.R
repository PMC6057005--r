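#' Direct and indirect SNP covariates
#'
#' For each SNP, the direct covariate is the individual's own dosage and the
#' indirect covariate is the summed dosages of its cage mates (range 0 to
#' 2 * (cage size - 1), i.e. 0-8 for cages of five). Fractional imputed
#' dosages propagate into the sums.
#'
#' @param geno \linkS4class{GenotypeMatrix} (imputed: no missing entries
#'   among the requested individuals).
#' @param cages \linkS4class{CageLayout}.
#' @param ids individuals (rows) to use, in order; default all cage members.
#' @param snps SNP ids or column indices; default all.
#' @return list with matrices \code{direct} and \code{indirect}
#'   (ids x SNPs).
#' @export
snpCovariates <- function(geno, cages, ids = NULL, snps = NULL) {
  if (is.null(ids)) ids <- cageMembers(cages)$id
  d <- dosages(geno)
  if (!all(ids %in% rownames(d)))
    stop("individual without genotype: ", setdiff(ids, rownames(d))[1])
  if (is.null(snps)) snps <- seq_len(ncol(d))
  d <- d[ids, snps, drop = FALSE]
  if (anyNA(d)) stop("missing dosages: impute before building covariates")
  cg <- cageOf(cages)[ids]
  if (anyNA(cg)) stop("individual without cage: ", ids[is.na(cg)][1])
  cgF <- factor(cg)
  S <- rowsum(d, cgF)                      # per-cage dosage sums
  indirect <- S[as.integer(cgF), , drop = FALSE] - d
  rownames(indirect) <- ids
  list(direct = d, indirect = indirect)
}

# Batched GLS scan over SNP pairs (direct, indirect) with the covariance
# fixed at the null fit. For each SNP the two covariates are fitted jointly
# with the null fixed effects via the bordered mixed-model equations; the
# 2x2 Schur complement gives estimates, SEs and 1-df Wald statistics. One
# covariance factorization (from the null fit) serves all SNPs.
.scanChunk <- function(engine, Cd, Ci) {
  k <- ncol(Cd)
  idxD <- seq_len(k); idxI <- k + seq_len(k)
  Cbig <- cbind(Cd, Ci)
  RC <- Cbig * engine$rw
  V <- as.matrix(Matrix::crossprod(engine$A, RC))
  S <- as.matrix(Matrix::solve(engine$ch, V))
  Qy <- drop(crossprod(RC, engine$y)) - drop(crossprod(V, engine$sol0))

  qdd0 <- colSums(Cd * RC[, idxD, drop = FALSE])
  qii0 <- colSums(Ci * RC[, idxI, drop = FALSE])
  qdd <- qdd0 - colSums(V[, idxD, drop = FALSE] * S[, idxD, drop = FALSE])
  qii <- qii0 - colSums(V[, idxI, drop = FALSE] * S[, idxI, drop = FALSE])
  qdi <- colSums(Cd * RC[, idxI, drop = FALSE]) -
    colSums(V[, idxD, drop = FALSE] * S[, idxI, drop = FALSE])

  out <- matrix(NA_real_, k, 8,
                dimnames = list(NULL, c("beta_D", "se_D", "stat_D", "p_D",
                                        "beta_I", "se_I", "stat_I", "p_I")))
  tolrel <- 1e-8
  for (j in seq_len(k)) {
    okD <- is.finite(qdd[j]) && qdd[j] > tolrel * max(qdd0[j], 1e-300)
    okI <- is.finite(qii[j]) && qii[j] > tolrel * max(qii0[j], 1e-300)
    if (okD && okI) {
      det2 <- qdd[j] * qii[j] - qdi[j]^2
      if (det2 > 1e-10 * qdd[j] * qii[j]) {
        Vb <- matrix(c(qii[j], -qdi[j], -qdi[j], qdd[j]), 2) / det2
        b <- Vb %*% c(Qy[idxD[j]], Qy[idxI[j]])
        out[j, c(1, 5)] <- b
        out[j, c(2, 6)] <- sqrt(diag(Vb))
      } else okD <- okI <- FALSE   # direct/indirect collinear: not estimable
    } else if (okD) {
      out[j, 1] <- Qy[idxD[j]] / qdd[j]
      out[j, 2] <- sqrt(1 / qdd[j])
    } else if (okI) {
      out[j, 5] <- Qy[idxI[j]] / qii[j]
      out[j, 6] <- sqrt(1 / qii[j])
    }
  }
  out[, "stat_D"] <- (out[, "beta_D"] / out[, "se_D"])^2
  out[, "stat_I"] <- (out[, "beta_I"] / out[, "se_I"])^2
  out[, "p_D"] <- ifelse(is.na(out[, "stat_D"]), 1,
                         stats::pchisq(out[, "stat_D"], 1, lower.tail = FALSE))
  out[, "p_I"] <- ifelse(is.na(out[, "stat_I"]), 1,
                         stats::pchisq(out[, "stat_I"], 1, lower.tail = FALSE))
  out
}

.expandRecords <- function(cv, ctx, multiplyT) {
  D <- cv$direct[ctx$recIndiv, , drop = FALSE]
  I <- cv$indirect[ctx$recIndiv, , drop = FALSE]
  if (multiplyT) { D <- D * ctx$tvec; I <- I * ctx$tvec }
  list(D = D, I = I)
}

.assembleScan <- function(fit, geno, snps, res) {
  m <- snpMap(geno)
  k <- match(snps, m$snp)
  maf <- mafs(geno)[k]
  tab <- data.frame(snp_id = m$snp[k], chrom = m$chrom[k], pos = m$pos[k],
                    maf = unname(maf), as.data.frame(res),
                    stringsAsFactors = FALSE)
  tab$p_D_gc <- NA_real_; tab$q_D <- NA_real_
  tab$p_I_gc <- NA_real_; tab$q_I <- NA_real_
  tab$model <- fit@model
  tab <- tab[, .scanCols]
  new("ScanResult", table = tab, model = fit@model, gc = list())
}

.runGaussScan <- function(fit, geno, cages, snps, multiplyT, chunk = 250L) {
  ctx <- fit@engine$ctx
  if (is.null(cages)) cages <- ctx$cages
  m <- snpMap(geno)
  if (is.null(snps)) snps <- m$snp
  if (is.numeric(snps)) snps <- m$snp[snps]
  res <- NULL
  for (lo in seq(1, length(snps), by = chunk)) {
    sel <- snps[lo:min(lo + chunk - 1L, length(snps))]
    cv <- snpCovariates(geno, cages, ids = ctx$ids, snps = sel)
    ex <- .expandRecords(cv, ctx, multiplyT)
    res <- rbind(res, .scanChunk(fit@engine, ex$D, ex$I))
  }
  .assembleScan(fit, geno, snps, res)
}

#' Genome scan under the survival-time model
#'
#' For each SNP, the direct and indirect covariates are fitted
#' simultaneously as fixed effects alongside the null model's location
#' effects, with all variance components fixed at the null REML estimates
#' (generalized least squares; one covariance factorization reused across
#' SNPs). Each effect is tested with a 1-df Wald chi-square.
#'
#' @param fit \linkS4class{NullModelFit} from \code{\link{fitNullSTM}}.
#' @param geno imputed \linkS4class{GenotypeMatrix}.
#' @param cages \linkS4class{CageLayout} (default: the layout of the fit).
#' @param snps SNP ids or indices to scan (default all).
#' @param chunk SNPs per internal batch.
#' @return a \linkS4class{ScanResult}.
#' @export
scanSTM <- function(fit, geno, cages = NULL, snps = NULL, chunk = 250L) {
  stopifnot(fit@model == "STM")
  .runGaussScan(fit, geno, cages, snps, multiplyT = FALSE, chunk = chunk)
}

#' Genome scan under the repeated-measures model
#'
#' As \code{\link{scanSTM}} but on the monthly records: the SNP covariates
#' enter multiplied by time, so effects are per-month slopes of the
#' survival curve.
#'
#' @param fit \linkS4class{NullModelFit} from \code{\link{fitNullRMM}}.
#' @inheritParams scanSTM
#' @return a \linkS4class{ScanResult}.
#' @export
scanRMM <- function(fit, geno, cages = NULL, snps = NULL, chunk = 100L) {
  stopifnot(fit@model == "RMM.t")
  .runGaussScan(fit, geno, cages, snps, multiplyT = TRUE, chunk = chunk)
}

#' Genome scan under the logit GLMM
#'
#' Per SNP, the penalized quasi-likelihood working-variate system is
#' re-solved with the variance components fixed at the null fit and the
#' direct and indirect covariates added to the fixed effects; the working
#' variates are iterated to convergence (with all variances at zero this
#' reduces to ordinary logistic regression). Wald tests are on the
#' linearized (logit) scale. Fitted probabilities are clamped to
#' [1e-6, 1 - 1e-6] under separation.
#'
#' @param fit \linkS4class{NullModelFit} from \code{\link{fitNullGLMM}}.
#' @param maxit,tol working-variate iteration cap and tolerance.
#' @inheritParams scanSTM
#' @return a \linkS4class{ScanResult}.
#' @export
scanGLMM <- function(fit, geno, cages = NULL, snps = NULL, maxit = 25L,
                     tol = 1e-8) {
  stopifnot(fit@model == "GLMM")
  ctx <- fit@engine$ctx
  if (is.null(cages)) cages <- ctx$cages
  m <- snpMap(geno)
  if (is.null(snps)) snps <- m$snp
  if (is.numeric(snps)) snps <- m$snp[snps]
  cv <- snpCovariates(geno, cages, ids = ctx$ids, snps = snps)
  X <- fit@engine$X
  Z <- ctx$Zall
  vc <- fit@varcomp
  Gpart <- Matrix::bdiag(lapply(seq_along(ctx$blocks), function(i) {
    b <- ctx$blocks[[i]]
    if (is.null(b$Ginv)) Matrix::Diagonal(ncol(b$Z), 1 / vc[i])
    else b$Ginv / vc[i]
  }))
  y <- ctx$y01
  eps <- 1e-6
  k <- length(snps)
  res <- matrix(NA_real_, k, 8,
                dimnames = list(NULL, c("beta_D", "se_D", "stat_D", "p_D",
                                        "beta_I", "se_I", "stat_I", "p_I")))
  for (j in seq_len(k)) {
    Cd <- cv$direct[ctx$recIndiv, j]
    Ci <- cv$indirect[ctx$recIndiv, j]
    Xp <- cbind(X, snpD = Cd, snpI = Ci)
    keep <- c(rep(TRUE, ncol(X)),
              stats::sd(Cd) > 1e-12, stats::sd(Ci) > 1e-12)
    sol <- .pqlFixedSolve(y, Xp[, keep, drop = FALSE], Z, Gpart,
                          eta0 = ctx$eta, eps = eps, maxit = maxit,
                          tol = tol)
    if (!is.null(sol)) {
      nms <- colnames(Xp)[keep]
      for (eff in c("D", "I")) {
        nm <- paste0("snp", eff)
        if (nm %in% nms) {
          i2 <- match(nm, nms)
          b <- sol$beta[i2]; s <- sol$se[i2]
          res[j, paste0(c("beta_", "se_", "stat_", "p_"), eff)] <-
            c(b, s, (b / s)^2,
              stats::pchisq((b / s)^2, 1, lower.tail = FALSE))
        }
      }
    }
  }
  res[, "p_D"][is.na(res[, "p_D"])] <- 1
  res[, "p_I"][is.na(res[, "p_I"])] <- 1
  .assembleScan(fit, geno, snps, res)
}

# fixed-variance PQL: iterate working variates for a given fixed-effect
# matrix; returns joint fixed-effect estimates and SEs on the logit scale,
# via the bordered sparse mixed-model equations
.pqlFixedSolve <- function(y, Xp, Z, Gpart, eta0, eps, maxit, tol) {
  eta <- eta0
  beta <- NULL
  p <- ncol(Xp)
  A <- cbind(methods::as(as.matrix(Xp), "CsparseMatrix"), Z)
  Gext <- Matrix::bdiag(Matrix::Diagonal(p, 0), Gpart)
  ch <- NULL
  for (it in seq_len(maxit)) {
    mu <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    Cmat <- Matrix::forceSymmetric(Matrix::crossprod(A * sqrt(w)) + Gext)
    ch <- tryCatch({
      if (is.null(ch)) Matrix::Cholesky(Cmat, LDL = FALSE, perm = TRUE)
      else Matrix::update(ch, Cmat)
    }, error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    sol <- as.numeric(Matrix::solve(ch, Matrix::crossprod(A, w * z)))
    betaNew <- sol[seq_len(p)]
    etaNew <- as.numeric(A %*% sol)
    done <- !is.null(beta) && max(abs(betaNew - beta)) < tol
    beta <- betaNew; eta <- etaNew
    if (done) break
  }
  Ip <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(ncol(A), p))
  covb <- as.matrix(Matrix::solve(ch, Ip))[seq_len(p), , drop = FALSE]
  list(beta = beta, se = sqrt(pmax(diag(covb), 0)), eta = eta)
}

#' Genomic control
#'
#' The inflation factor lambda is the median observed 1-df Wald statistic
#' divided by the null chi-square median (0.4549), computed separately for
#' direct and indirect effects. When lambda exceeds \code{threshold}
#' (strictly), statistics are divided by lambda and p-values recomputed
#' before any FDR step; otherwise p-values are passed through unchanged.
#' With fewer than \code{minSnps} statistics lambda is reported but the
#' correction is refused with a warning.
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param threshold correction trigger (strict inequality).
#' @param minSnps minimum number of SNPs for a stable median.
#' @return the \linkS4class{ScanResult} with \code{p_D_gc}, \code{p_I_gc}
#'   filled and a \code{gc} slot recording both lambdas.
#' @export
genomicControl <- function(scan, threshold = 1.10, minSnps = 10L) {
  tab <- scanTable(scan)
  med0 <- stats::qchisq(0.5, df = 1)
  doSide <- function(stat, p) {
    ok <- is.finite(stat)
    lam <- stats::median(stat[ok]) / med0
    if (sum(ok) < minSnps) {
      warning(sprintf("genomic control refused: only %d usable statistics",
                      sum(ok)))
      return(list(lambda = lam, applied = FALSE, p = p))
    }
    if (lam > threshold) {
      pg <- p
      pg[ok] <- stats::pchisq(stat[ok] / lam, 1, lower.tail = FALSE)
      list(lambda = lam, applied = TRUE, p = pg)
    } else list(lambda = lam, applied = FALSE, p = p)
  }
  d <- doSide(tab$stat_D, tab$p_D)
  i <- doSide(tab$stat_I, tab$p_I)
  tab$p_D_gc <- d$p
  tab$p_I_gc <- i$p
  gc <- list(lambda_direct = d$lambda, lambda_indirect = i$lambda,
             applied_direct = d$applied, applied_indirect = i$applied)
  new("ScanResult", table = tab, model = scan@model, gc = gc)
}

#' Agreement between two scans
#'
#' Pearson correlation of -log10 p-values over the common SNP panel,
#' separately for direct and indirect effects; SNPs not estimable in either
#' scan are excluded.
#'
#' @param scan1,scan2 \linkS4class{ScanResult} objects on the same panel.
#' @param useGC correlate GC-adjusted p-values when available.
#' @return named numeric c(direct, indirect).
#' @export
modelAgreement <- function(scan1, scan2, useGC = FALSE) {
  t1 <- scanTable(scan1); t2 <- scanTable(scan2)
  common <- intersect(t1$snp_id, t2$snp_id)
  if (length(common) < 3) stop("fewer than 3 common SNPs")
  k1 <- match(common, t1$snp_id); k2 <- match(common, t2$snp_id)
  pick <- function(tab, eff) {
    col <- paste0("p_", eff, if (useGC) "_gc" else "")
    tab[[col]]
  }
  corOn <- function(eff) {
    x <- -log10(pick(t1, eff)[k1]); y <- -log10(pick(t2, eff)[k2])
    ok <- is.finite(x) & is.finite(y)
    stats::cor(x[ok], y[ok])
  }
  c(direct = corOn("D"), indirect = corOn("I"))
}
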