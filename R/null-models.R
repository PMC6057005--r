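.locFactor <- function(cages, ids) {
  mem <- cageMembers(cages)
  f <- factor(mem$location[match(ids, mem$id)])
  if (anyNA(f)) stop("phenotyped individual without a cage: ",
                     ids[is.na(f)][1])
  droplevels(f)
}

.fixedX <- function(loc) {
  if (nlevels(loc) > 1) stats::model.matrix(~loc)
  else matrix(1, length(loc), 1, dimnames = list(NULL, "(Intercept)"))
}

.pedBlock <- function(ids, Ainv) {
  pid <- match(ids, rownames(Ainv))
  if (anyNA(pid)) stop("individual missing from the relationship matrix: ",
                       ids[is.na(pid)][1])
  Z <- Matrix::sparseMatrix(i = seq_along(ids), j = pid, x = 1,
                            dims = c(length(ids), nrow(Ainv)),
                            dimnames = list(ids, rownames(Ainv)))
  ld <- 2 * as.numeric(Matrix::determinant(
    Matrix::Cholesky(Ainv, LDL = FALSE), sqrt = TRUE)$modulus)
  list(Z = Z, Ginv = Ainv, logdetGinv = ld)
}

#' Fit the survival-time null model (STM) by REML
#'
#' Linear animal model for survival time: fixed wing-row-level (location)
#' effects plus random polygenic effects with covariance A sigma2_a, iid
#' cage effects and iid residuals. With family-structured cages the
#' polygenic term absorbs both direct and indirect genetic variation, so
#' sigma2_a estimates the total heritable variance. SNP scans fix the
#' variance components at this fit.
#'
#' @param phenotypes a \linkS4class{PhenotypeSet}.
#' @param cages a \linkS4class{CageLayout}.
#' @param pedigree a \linkS4class{Pedigree} (used when \code{Ainv} missing).
#' @param Ainv optional precomputed sparse A-inverse from
#'   \code{\link{buildAinv}}.
#' @param includeCage fit the random cage effect (TRUE for the study design).
#' @param ... passed to \code{\link{fitLMM}} (e.g. \code{start},
#'   \code{control}, \code{se}).
#' @return a \linkS4class{NullModelFit} with components \code{a},
#'   \code{cage}, \code{residual} (days^2).
#' @export
fitNullSTM <- function(phenotypes, cages, pedigree = NULL, Ainv = NULL,
                       includeCage = TRUE, ...) {
  s <- survivalDays(phenotypes)
  ids <- s$id
  y <- as.numeric(s$survivalDay)
  if (stats::var(y) == 0) y <- y + 0  # bounds handle the degenerate case
  if (is.null(Ainv)) Ainv <- buildAinv(pedigree)
  loc <- .locFactor(cages, ids)
  X <- .fixedX(loc)
  blocks <- list(a = .pedBlock(ids, Ainv))
  cg <- factor(cageOf(cages)[ids])
  if (includeCage) {
    blocks$cage <- list(Z = Matrix::sparseMatrix(
      i = seq_along(ids), j = as.integer(cg), x = 1,
      dims = c(length(ids), nlevels(cg)),
      dimnames = list(ids, levels(cg))), Ginv = NULL)
  }
  vy <- stats::var(y)
  start <- c(a = 0.1 * vy, cage = if (includeCage) 0.1 * vy,
             residual = 0.8 * vy)
  fit <- fitLMM(y, X, blocks, start = start, ...)
  fit$engine$ctx <- list(model = "STM", ids = ids,
                         recIndiv = seq_along(ids), tvec = NULL,
                         cages = cages, loc = loc)
  new("NullModelFit", model = "STM", varcomp = fit$varcomp,
      varcompSE = fit$varcompSE, fixef = fit$fixef, logLik = fit$logLik,
      engine = fit$engine, sigmaP2 = sum(fit$varcomp))
}

#' Fit the repeated-measures random-regression null model (RMM.t) by REML
#'
#' Linear mixed model for the monthly 0/1 survival records with random
#' regressions on time t_m = 1..13 (months since the start of the laying
#' period): polygenic slope a_i t_m, permanent-environment slope PE_i t_m,
#' permanent cage slope cage_k t_m, a cage-by-month effect cage_km, fixed
#' location-specific polynomial survival curves (order \code{polyOrder}),
#' and a separate residual variance for every month.
#'
#' @param monthly 0/1 matrix from \code{\link{monthlyRecords}} (individuals
#'   x months, rownames = ids).
#' @param cages,pedigree,Ainv as in \code{\link{fitNullSTM}}.
#' @param polyOrder order of the fixed time polynomial (default 6,
#'   orthogonal basis).
#' @param residLower absolute floor for the month-specific residual
#'   variances (default 1e-3 on the 0/1 record scale). Months without any
#'   mortality have residual variance 0 and an unbounded REML likelihood;
#'   the floor caps their weight at 1000 instead of letting constant months
#'   dominate the fit.
#' @param se compute asymptotic SEs of the 17 variance components (a
#'   finite-difference Hessian over all components; costly at full size,
#'   off by default).
#' @param control optimizer control for \code{\link{fitLMM}}.
#' @param ... passed to \code{\link{fitLMM}}.
#' @return a \linkS4class{NullModelFit} with components \code{a} (genetic
#'   slope variance), \code{pe}, \code{cageSlope}, \code{cageMonth} and 13
#'   month residual variances.
#' @export
fitNullRMM <- function(monthly, cages, pedigree = NULL, Ainv = NULL,
                       polyOrder = 6, residLower = 1e-3, se = FALSE,
                       control = list(factr = 1e10, maxit = 300), ...) {
  ids <- rownames(monthly)
  n <- nrow(monthly)
  if (is.null(Ainv)) Ainv <- buildAinv(pedigree)
  # months without any mortality carry no contrasts and have an unbounded
  # REML likelihood (residual variance 0); exclude their records
  keepM <- which(apply(monthly, 2, stats::var) > 0)
  if (!length(keepM)) keepM <- seq_len(ncol(monthly))
  if (length(keepM) < ncol(monthly))
    message(sprintf("fitNullRMM: dropping %d constant month(s): %s",
                    ncol(monthly) - length(keepM),
                    paste(setdiff(seq_len(ncol(monthly)), keepM),
                          collapse = ", ")))
  nm <- length(keepM)
  y <- as.vector(monthly[, keepM, drop = FALSE])  # month-major record order
  tvec <- rep(keepM, each = n)                    # true month numbers
  recIndiv <- rep(seq_len(n), nm)
  loc <- .locFactor(cages, ids)
  X <- .rmmFixedX(loc[recIndiv], tvec, polyOrder)

  cg <- factor(cageOf(cages)[ids])
  pidB <- .pedBlock(ids, Ainv)
  N <- n * nm
  mIdx <- rep(seq_len(nm), each = n)              # index into kept months
  Za <- Matrix::sparseMatrix(i = seq_len(N),
                             j = rep(match(ids, rownames(Ainv)), nm),
                             x = tvec, dims = c(N, nrow(Ainv)),
                             dimnames = list(NULL, rownames(Ainv)))
  Zpe <- Matrix::sparseMatrix(i = seq_len(N), j = recIndiv, x = tvec,
                              dims = c(N, n), dimnames = list(NULL, ids))
  Zct <- Matrix::sparseMatrix(i = seq_len(N),
                              j = as.integer(cg)[recIndiv], x = tvec,
                              dims = c(N, nlevels(cg)),
                              dimnames = list(NULL, levels(cg)))
  km <- as.integer(cg)[recIndiv] + (mIdx - 1L) * nlevels(cg)
  Zkm <- Matrix::sparseMatrix(i = seq_len(N), j = km, x = 1,
                              dims = c(N, nlevels(cg) * nm))
  blocks <- list(
    a = list(Z = Za, Ginv = pidB$Ginv, logdetGinv = pidB$logdetGinv),
    pe = list(Z = Zpe, Ginv = NULL),
    cageSlope = list(Z = Zct, Ginv = NULL),
    cageMonth = list(Z = Zkm, Ginv = NULL))
  months <- factor(tvec, levels = keepM)

  vm <- pmax(apply(monthly[, keepM, drop = FALSE], 2, stats::var), residLower)
  start <- c(a = 2e-4, pe = 2e-4, cageSlope = 2e-4, cageMonth = 0.01,
             stats::setNames(vm, paste0("residual.", keepM)))
  fit <- fitLMM(y, X, blocks, residGroups = months, start = start,
                residLower = residLower, se = se, control = control, ...)
  fit$engine$ctx <- list(model = "RMM.t", ids = ids, recIndiv = recIndiv,
                         tvec = tvec, cages = cages, loc = loc,
                         months = months)
  new("NullModelFit", model = "RMM.t", varcomp = fit$varcomp,
      varcompSE = fit$varcompSE, fixef = fit$fixef, logLik = fit$logLik,
      engine = fit$engine, sigmaP2 = NA_real_)
}

.rmmFixedX <- function(locRec, tvec, polyOrder) {
  deg <- min(polyOrder, length(unique(tvec)) - 1)
  if (deg < 1)
    return(.fixedX(droplevels(locRec)))
  tp <- stats::poly(tvec, degree = deg)
  if (nlevels(locRec) > 1)
    stats::model.matrix(~ locRec * tp)
  else stats::model.matrix(~ tp)
}

#' Fit the logit generalized linear mixed null model (GLMM) by PQL
#'
#' Binomial GLMM with logit link for the monthly 0/1 records: fixed
#' location-by-time polynomial, random polygenic intercept a_i (covariance
#' A sigma2_a), cage-by-month effect and individual permanent-environment
#' effect; no genetic regression on time because the link function carries
#' the change in variance over time. Fitted by penalized quasi-likelihood:
#' working variates z = eta + (y - mu)/(mu(1-mu)) with weights mu(1-mu) are
#' iterated against REML fits of the linearized model. Fitted probabilities
#' are clamped to [1e-6, 1-1e-6] under separation, with a message.
#'
#' @inheritParams fitNullRMM
#' @param maxitPQL,tolPQL outer-loop iteration cap and convergence tolerance
#'   on variance components and fixed effects.
#' @param varFixed optional named vector c(a=, cageMonth=, pe=) of fixed
#'   variance components: the REML step is skipped and only the working
#'   variates are iterated (with all variances near zero this reduces to
#'   ordinary logistic regression).
#' @return a \linkS4class{NullModelFit} with components \code{a},
#'   \code{cageMonth}, \code{pe} on the logit^2 scale.
#' @export
fitNullGLMM <- function(monthly, cages, pedigree = NULL, Ainv = NULL,
                        polyOrder = 6, maxitPQL = 20, tolPQL = 1e-4,
                        varFixed = NULL, ...) {
  ids <- rownames(monthly)
  n <- nrow(monthly)
  if (is.null(Ainv)) Ainv <- buildAinv(pedigree)
  keepM <- which(apply(monthly, 2, stats::var) > 0)
  if (!length(keepM)) keepM <- seq_len(ncol(monthly))
  if (length(keepM) < ncol(monthly))
    message(sprintf("fitNullGLMM: dropping %d constant month(s)",
                    ncol(monthly) - length(keepM)))
  nm <- length(keepM)
  y <- as.vector(monthly[, keepM, drop = FALSE])
  tvec <- rep(keepM, each = n)
  recIndiv <- rep(seq_len(n), nm)
  mIdx <- rep(seq_len(nm), each = n)
  loc <- .locFactor(cages, ids)
  X <- .rmmFixedX(loc[recIndiv], tvec, polyOrder)
  cg <- factor(cageOf(cages)[ids])
  N <- n * nm
  pidB <- .pedBlock(ids, Ainv)
  Za <- Matrix::sparseMatrix(i = seq_len(N),
                             j = rep(match(ids, rownames(Ainv)), nm), x = 1,
                             dims = c(N, nrow(Ainv)))
  km <- as.integer(cg)[recIndiv] + (mIdx - 1L) * nlevels(cg)
  Zkm <- Matrix::sparseMatrix(i = seq_len(N), j = km, x = 1,
                              dims = c(N, nlevels(cg) * nm))
  Zpe <- Matrix::sparseMatrix(i = seq_len(N), j = recIndiv, x = 1,
                              dims = c(N, n))
  blocks <- list(
    a = list(Z = Za, Ginv = pidB$Ginv, logdetGinv = pidB$logdetGinv),
    cageMonth = list(Z = Zkm, Ginv = NULL),
    pe = list(Z = Zpe, Ginv = NULL))
  Zall <- cbind(Za, Zkm, Zpe)

  eps <- 1e-6
  if (!is.null(varFixed)) {
    varFixed <- pmax(varFixed[c("a", "cageMonth", "pe")], 1e-8)
    Gpart <- Matrix::bdiag(
      blocks$a$Ginv / varFixed[["a"]],
      Matrix::Diagonal(ncol(Zkm), 1 / varFixed[["cageMonth"]]),
      Matrix::Diagonal(ncol(Zpe), 1 / varFixed[["pe"]]))
    mu0 <- pmin(pmax((y + 0.5) / 2, eps), 1 - eps)
    sol <- .pqlFixedSolve(y, X, Zall, Gpart, eta0 = stats::qlogis(mu0),
                          eps = eps, maxit = 4 * maxitPQL, tol = tolPQL * 1e-2)
    if (is.null(sol)) stop("GLMM working-variate solve failed")
    eng <- list(X = X,
                ctx = list(model = "GLMM", ids = ids, recIndiv = recIndiv,
                           tvec = tvec, cages = cages, loc = loc,
                           y01 = y, eta = sol$eta, Zall = Zall,
                           blocks = blocks, clamped = NA_integer_))
    return(new("NullModelFit", model = "GLMM", varcomp = varFixed,
               varcompSE = stats::setNames(rep(NA_real_, 3), names(varFixed)),
               fixef = stats::setNames(sol$beta, colnames(X)),
               logLik = NA_real_, engine = eng, sigmaP2 = NA_real_))
  }
  mu <- pmin(pmax((y + 0.5) / 2, eps), 1 - eps)
  eta <- stats::qlogis(mu)
  vc <- c(a = 0.1, cageMonth = 0.1, pe = 0.1)
  clampTotal <- 0L
  fit <- NULL
  for (it in seq_len(maxitPQL)) {
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- fitLMM(z, X, blocks, rFixed = 1 / w,
                  start = vc, se = (it == maxitPQL), ...)
    etaNew <- drop(fit$engine$X %*% fit$fixef) +
      as.numeric(Zall %*% unlist(fit$blup, use.names = FALSE))
    muNew <- stats::plogis(etaNew)
    nClamp <- sum(muNew < eps | muNew > 1 - eps)
    clampTotal <- clampTotal + nClamp
    muNew <- pmin(pmax(muNew, eps), 1 - eps)
    delta <- max(abs(log(pmax(fit$varcomp, 1e-10)) - log(pmax(vc, 1e-10))),
                 max(abs(etaNew - eta)) / (1 + max(abs(eta))))
    vc <- fit$varcomp
    eta <- etaNew; mu <- muNew
    if (delta < tolPQL) break
  }
  if (clampTotal > 0)
    message(sprintf("fitNullGLMM: clamped %d fitted probabilities (separation)",
                    clampTotal))
  if (!length(fit$varcompSE) || all(is.na(fit$varcompSE))) {
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- fitLMM(z, X, blocks, rFixed = 1 / w, start = vc, se = TRUE, ...)
  }
  fit$engine$ctx <- list(model = "GLMM", ids = ids, recIndiv = recIndiv,
                         tvec = tvec, cages = cages, loc = loc,
                         y01 = y, eta = eta, Zall = Zall, blocks = blocks,
                         clamped = clampTotal)
  new("NullModelFit", model = "GLMM", varcomp = fit$varcomp,
      varcompSE = fit$varcompSE, fixef = fit$fixef, logLik = fit$logLik,
      engine = fit$engine, sigmaP2 = NA_real_)
}

#' Total heritable variance ratio and genetic standard deviation
#'
#' For the survival-time model, T2 = sigma2_a / sigma2_P and sigmaA =
#' sqrt(sigma2_a) in days. With family-structured cages sigma2_a is the
#' total (direct plus indirect) heritable variance, so T2 is the ratio of
#' total heritable to phenotypic variance.
#'
#' @param object a \linkS4class{NullModelFit} from \code{\link{fitNullSTM}},
#'   or the numeric sigma2_a.
#' @param sigmaP2 phenotypic variance (required for the numeric method).
#' @return named numeric vector c(T2, sigmaA).
#' @export
setGeneric("totalHeritableParams",
           function(object, sigmaP2) standardGeneric("totalHeritableParams"))

#' @rdname totalHeritableParams
#' @export
setMethod("totalHeritableParams", "NullModelFit", function(object, sigmaP2) {
  if (object@model != "STM")
    stop("totalHeritableParams is defined for the survival-time model")
  if (missing(sigmaP2)) sigmaP2 <- object@sigmaP2
  totalHeritableParams(unname(object@varcomp["a"]), sigmaP2)
})

#' @rdname totalHeritableParams
#' @export
setMethod("totalHeritableParams", "numeric", function(object, sigmaP2) {
  if (sigmaP2 <= 0) stop("sigmaP2 must be positive")
  c(T2 = object / sigmaP2, sigmaA = sqrt(object))
})
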