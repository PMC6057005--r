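# REML for Gaussian mixed models y = Xb + sum_i Z_i u_i + e with
# var(u_i) = sigma_i^2 G0_i (G0_i given through its sparse inverse, or
# identity) and a diagonal residual: one variance, one variance per record
# group (e.g. month), or a fixed weight vector (PQL working models).
#
# All computations run through the sparse mixed-model equations
#   C = [X Z]' R^-1 [X Z] + blkdiag(0, Ginv_i / sigma_i^2)
# using the REML identity  -2 l = log|R| + log|G| + log|C| + y'Py  with
# y'Py = y'R^-1y - sol' [X Z]'R^-1 y, so each likelihood evaluation is one
# cached-pattern sparse Cholesky factorization plus one solve. The
# criterion is maximized directly over log-variances (L-BFGS-B); with a
# single homoscedastic residual the residual variance is profiled out and
# the search runs over variance ratios only.

.remlPrep <- function(y, X, blocks, residGroups = NULL, rFixed = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  Xs <- methods::as(X, "CsparseMatrix")
  Z <- do.call(cbind, lapply(blocks, function(b) b$Z))
  A <- cbind(Xs, Z)
  p <- ncol(X)
  q <- vapply(blocks, function(b) ncol(b$Z), integer(1))
  ldG <- vapply(blocks, function(b) {
    if (is.null(b$Ginv)) 0 else
      if (!is.null(b$logdetGinv)) b$logdetGinv else
        2 * as.numeric(Matrix::determinant(
          Matrix::Cholesky(b$Ginv, LDL = FALSE), sqrt = TRUE)$modulus)
  }, numeric(1))
  GinvList <- lapply(blocks, function(b) b$Ginv)

  if (is.null(residGroups)) residGroups <- factor(rep(1L, n))
  residGroups <- droplevels(as.factor(residGroups))
  gsplit <- split(seq_len(n), residGroups)
  if (is.null(rFixed)) {
    AtAg <- lapply(gsplit, function(ix)
      Matrix::forceSymmetric(Matrix::crossprod(A[ix, , drop = FALSE])))
    Atyg <- lapply(gsplit, function(ix)
      as.numeric(Matrix::crossprod(A[ix, , drop = FALSE], y[ix])))
    ytyg <- vapply(gsplit, function(ix) sum(y[ix]^2), numeric(1))
  } else {
    rw <- 1 / rFixed
    AtAg <- list(Matrix::forceSymmetric(Matrix::crossprod(A, A * rw)))
    Atyg <- list(as.numeric(Matrix::crossprod(A, y * rw)))
    ytyg <- sum(y^2 * rw)
  }
  # G-side components, padded to the full bordered dimension
  dimC <- p + sum(q)
  off <- p + c(0L, cumsum(q))[seq_along(q)]
  Gcomp <- lapply(seq_along(blocks), function(i) {
    if (is.null(GinvList[[i]])) {
      jj <- off[i] + seq_len(q[i])
      Matrix::sparseMatrix(i = jj, j = jj, x = rep(1, q[i]),
                           dims = c(dimC, dimC), symmetric = TRUE)
    } else {
      g <- methods::as(Matrix::forceSymmetric(GinvList[[i]]), "TsparseMatrix")
      Matrix::sparseMatrix(i = g@i + 1L + off[i], j = g@j + 1L + off[i],
                           x = g@x, dims = c(dimC, dimC), symmetric = TRUE)
    }
  })
  # fixed-pattern template and index maps for fast per-evaluation assembly
  comps <- c(AtAg, Gcomp)
  comps <- lapply(comps, function(M)
    methods::as(Matrix::forceSymmetric(M, "U"), "CsparseMatrix"))
  tmpl <- Reduce(`+`, lapply(comps, function(M) {
    M@x[] <- 1; M
  }))
  keyT <- .cscKeys(tmpl, dimC)
  compIdx <- lapply(comps, function(M) match(.cscKeys(M, dimC), keyT))
  compX <- lapply(comps, function(M) M@x)
  tmpl@x[] <- 0

  list(y = y, X = X, A = A, Z = Z, p = p, q = q, ldG = ldG, Ginv = GinvList,
       n = n, groups = residGroups, gsplit = gsplit,
       AtAg = AtAg, Atyg = Atyg, ytyg = ytyg, rFixed = rFixed,
       tmpl = tmpl, compIdx = compIdx, compX = compX,
       nGrpComp = length(AtAg))
}

.cscKeys <- function(M, dimC) {
  j <- rep.int(seq_len(ncol(M)), diff(M@p))
  as.numeric(M@i) * dimC + j
}

# core evaluation; rinvByGroup = list of 1/sigma_g^2 (NULL when rFixed)
.remlCore <- function(prep, s2b, rinvByGroup, logdetR, env,
                      solutions = FALSE) {
  coefs <- c(if (is.null(prep$rFixed)) unlist(rinvByGroup) else 1, 1 / s2b)
  x <- numeric(length(prep$tmpl@x))
  for (k in seq_along(coefs)) {
    ix <- prep$compIdx[[k]]
    x[ix] <- x[ix] + coefs[k] * prep$compX[[k]]
  }
  C <- prep$tmpl
  C@x <- x
  if (is.null(prep$rFixed)) {
    Aty <- Reduce(`+`, Map(`*`, prep$Atyg, rinvByGroup))
    yRy <- sum(unlist(prep$ytyg) * unlist(rinvByGroup))
  } else {
    Aty <- prep$Atyg[[1]]
    yRy <- prep$ytyg
  }
  ch <- tryCatch({
    if (is.null(env$chol)) Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    else Matrix::update(env$chol, C)
  }, error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  env$chol <- ch
  sol <- as.numeric(Matrix::solve(ch, Aty))
  yPy <- max(yRy - sum(Aty * sol), 1e-300)
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  logdetG <- sum(prep$q * log(s2b)) - sum(prep$ldG)
  list(m2l = logdetR + logdetG + logdetC + yPy,
       yPy = yPy, sol = sol, ch = ch, logdetC = logdetC, logdetG = logdetG)
}

# -2 REML logLik, full parameterization: theta = log block variances then
# log residual group variances (absent when rFixed is given)
.remlEvalFull <- function(theta, prep, env) {
  nb <- length(prep$q)
  s2b <- exp(theta[seq_len(nb)])
  if (is.null(prep$rFixed)) {
    s2r <- exp(theta[nb + seq_along(prep$gsplit)])
    rinv <- as.list(1 / s2r)
    logdetR <- sum(lengths(prep$gsplit) * log(s2r))
  } else {
    rinv <- NULL
    logdetR <- sum(log(prep$rFixed))
  }
  cr <- .remlCore(prep, s2b, rinv, logdetR, env)
  if (is.null(cr)) return(1e10)
  cr$m2l
}

# profiled: single residual group, theta = log variance ratios gamma_i
.remlEvalProf <- function(theta, prep, env) {
  gam <- exp(theta)
  cr <- .remlCore(prep, gam, list(1), 0, env)
  if (is.null(cr)) return(1e10)
  np <- prep$n - prep$p
  np * log(cr$yPy / np) + cr$logdetG + cr$logdetC + np
}

#' Fit a Gaussian linear mixed model by REML
#'
#' Low-level engine behind \code{\link{fitNullSTM}}, \code{\link{fitNullRMM}}
#' and the working-model steps of \code{\link{fitNullGLMM}}. Maximizes the
#' REML log-likelihood over log variance components with L-BFGS-B (profiling
#' the residual variance out when it is a single homoscedastic component),
#' evaluating the likelihood through one sparse mixed-model-equations
#' Cholesky factorization per evaluation.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full column rank).
#' @param blocks named list of random-effect blocks, each a list with
#'   \code{Z} (sparse design), optional \code{Ginv} (sparse inverse of the
#'   correlation structure, e.g. the pedigree A-inverse) and optional
#'   \code{logdetGinv} (log determinant of Ginv, cached).
#' @param residGroups optional factor (length n) giving one residual
#'   variance per level (e.g. month-specific residuals).
#' @param rFixed optional fixed residual variance vector (length n); no
#'   residual parameter is estimated (penalized quasi-likelihood working
#'   models).
#' @param start optional named start values on the variance scale (block
#'   names, then \code{residual} or \code{residual.<level>}).
#' @param boundFrac lower bound for components as a fraction of var(y).
#' @param residLower optional absolute lower bound for residual-group
#'   variances (guards against unbounded likelihoods when a group's records
#'   are constant, e.g. months without mortality).
#' @param control list passed to \code{optim}.
#' @param se compute asymptotic standard errors from the observed
#'   information of the log-variances (delta method).
#' @return list with \code{varcomp}, \code{varcompSE}, \code{fixef},
#'   \code{fixefVcov}, \code{blup}, \code{logLik} (-0.5 times the minimized
#'   criterion, up to a constant), \code{converged} and \code{engine} (the
#'   covariance factorization handle reused by GLS scans).
#' @export
fitLMM <- function(y, X, blocks, residGroups = NULL, rFixed = NULL,
                   start = NULL, boundFrac = 1e-8, residLower = NULL,
                   control = list(factr = 1e7, maxit = 500), se = TRUE) {
  prep <- .remlPrep(y, X, blocks, residGroups, rFixed)
  env <- new.env(parent = emptyenv()); env$chol <- NULL
  nb <- length(prep$q)
  vy <- max(stats::var(y), 1e-12)
  profiled <- is.null(rFixed) && length(prep$gsplit) == 1L

  if (profiled) {
    th0 <- rep(log(0.1), nb)
    if (!is.null(start)) {
      se2 <- if ("residual" %in% names(start)) start[["residual"]] else 0.5 * vy
      th0 <- log(pmax(start[names(blocks)], boundFrac * vy) / se2)
    }
    opt <- stats::optim(th0, .remlEvalProf, prep = prep, env = env,
                        method = "L-BFGS-B",
                        lower = rep(log(1e-8), nb), upper = rep(log(1e8), nb),
                        control = control)
    gam <- exp(opt$par)
    cr <- .remlCore(prep, gam, list(1), 0, env)
    se2 <- cr$yPy / (prep$n - prep$p)
    varcomp <- c(gam * se2, se2)
    names(varcomp) <- c(names(blocks), "residual")
  } else {
    ngrp <- if (is.null(rFixed)) length(prep$gsplit) else 0L
    nmAll <- c(names(blocks),
               if (ngrp) paste0("residual.", names(prep$gsplit)))
    th0 <- c(rep(log(0.1 * vy), nb), rep(log(0.5 * vy), ngrp))
    if (!is.null(start)) {
      s <- start[nmAll]
      s[is.na(s)] <- exp(th0)[is.na(s)]
      th0 <- log(pmax(s, boundFrac * vy))
    }
    lower <- rep(log(boundFrac * vy), nb + ngrp)
    if (!is.null(residLower) && ngrp)
      lower[nb + seq_len(ngrp)] <- log(residLower)
    th0 <- pmax(th0, lower)
    opt <- stats::optim(th0, .remlEvalFull, prep = prep, env = env,
                        method = "L-BFGS-B", lower = lower,
                        upper = rep(log(1e6 * max(vy, 1)), nb + ngrp),
                        control = control)
    varcomp <- stats::setNames(exp(opt$par), nmAll)
  }

  # final pass on the natural scale: estimates, BLUPs, engine handle
  s2b <- varcomp[seq_len(nb)]
  if (is.null(rFixed)) {
    s2r <- if (profiled) varcomp[["residual"]]
           else unname(varcomp[nb + seq_along(prep$gsplit)])
    rinv <- as.list(1 / s2r)
    logdetR <- sum(lengths(prep$gsplit) * log(s2r))
    rw <- rep(NA_real_, prep$n)
    for (g in seq_along(prep$gsplit)) rw[prep$gsplit[[g]]] <- 1 / s2r[[g]]
  } else {
    rinv <- NULL
    logdetR <- sum(log(prep$rFixed))
    rw <- 1 / prep$rFixed
  }
  cr <- .remlCore(prep, s2b, rinv, logdetR, env, solutions = TRUE)
  if (is.null(cr)) stop("REML: factorization failed at the optimum")

  vse <- rep(NA_real_, length(varcomp))
  if (se) {
    H <- tryCatch(
      stats::optimHess(log(varcomp), .remlEvalFull, prep = prep, env = env),
      error = function(e) NULL)
    if (!is.null(H)) {
      Vth <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(Vth)) {
        dv <- diag(Vth); dv[dv < 0] <- NA
        vse <- varcomp * sqrt(dv)     # delta method from the log scale
      }
    }
    cr <- .remlCore(prep, s2b, rinv, logdetR, env, solutions = TRUE)
  }

  p <- prep$p
  bhat <- cr$sol[seq_len(p)]
  u <- cr$sol[-seq_len(p)]
  # fixed-effect covariance: fixed block of the MME inverse
  Ip <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(p + sum(prep$q), p))
  fixefVcov <- as.matrix(Matrix::solve(cr$ch, Ip))[seq_len(p), , drop = FALSE]
  dimnames(fixefVcov) <- list(colnames(prep$X), colnames(prep$X))
  ublocks <- split(u, rep(seq_len(nb), prep$q))
  names(ublocks) <- names(blocks)
  for (i in seq_len(nb)) names(ublocks[[i]]) <- colnames(blocks[[i]]$Z)

  Aty <- if (is.null(prep$rFixed))
    Reduce(`+`, Map(`*`, prep$Atyg, rinv)) else prep$Atyg[[1]]
  engine <- list(A = prep$A, rw = rw, ch = cr$ch, sol0 = cr$sol,
                 Aty0 = as.numeric(Aty), y = prep$y,
                 yRy = sum(prep$y^2 * rw), n = prep$n, p = p,
                 X = prep$X)
  list(varcomp = varcomp, varcompSE = stats::setNames(vse, names(varcomp)),
       fixef = stats::setNames(bhat, colnames(prep$X)),
       fixefVcov = fixefVcov, blup = ublocks,
       logLik = -0.5 * cr$m2l, converged = opt$convergence == 0,
       engine = engine)
}

#' Generalized least squares for extra fixed covariates
#'
#' Estimates the coefficients of additional fixed-effect columns \code{C}
#' jointly with the null model's fixed effects, with the phenotypic
#' covariance fixed at the null fit; the null fit's single sparse
#' factorization is reused (bordered mixed-model equations via the Schur
#' complement) and the null fit itself is never modified.
#'
#' @param engine the \code{engine} element of a \code{\link{fitLMM}} fit or
#'   of a \linkS4class{NullModelFit}.
#' @param C numeric matrix of covariate columns (n x k).
#' @return list with \code{beta}, \code{se}, \code{stat} (1-df Wald),
#'   \code{p}, \code{estimable} (logical) and \code{vcov} (k x k).
#' @export
glsFixed <- function(engine, C) {
  C <- as.matrix(C)
  k <- ncol(C)
  RC <- C * engine$rw
  V <- as.matrix(Matrix::crossprod(engine$A, RC))
  S <- as.matrix(Matrix::solve(engine$ch, V))
  Q <- crossprod(C, RC) - crossprod(V, S)
  Q <- (Q + t(Q)) / 2
  Qy <- drop(crossprod(RC, engine$y)) - drop(crossprod(V, engine$sol0))
  raw <- colSums(C * RC)

  scaleOK <- diag(Q) > 1e-8 * pmax(raw, 1e-300)
  beta <- se <- rep(NA_real_, k)
  vc <- matrix(NA_real_, k, k)
  estim <- scaleOK
  if (any(estim)) {
    solveSub <- function(idx) {
      cQ <- chol(Q[idx, idx, drop = FALSE])
      if (min(diag(cQ))^2 < 1e-10 * max(diag(Q)[idx])) stop("collinear")
      chol2inv(cQ)
    }
    ok <- tryCatch({
      Vce <- solveSub(which(estim)); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      # rank deficiency among candidates: greedily keep earlier columns,
      # dropping later-positioned collinear ones
      sel <- logical(k)
      for (j in which(estim)) {
        sel[j] <- tryCatch({
          solveSub(c(which(sel), j)); TRUE
        }, error = function(e) FALSE)
      }
      estim <- sel
      Vce <- if (any(estim)) solveSub(which(estim)) else NULL
    }
    if (any(estim)) {
      beta[estim] <- drop(Vce %*% Qy[estim])
      se[estim] <- sqrt(diag(Vce))
      vc[estim, estim] <- Vce
    }
  }
  stat <- (beta / se)^2
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[!estim] <- 1
  list(beta = beta, se = se, stat = stat, p = p, estimable = estim, vcov = vc)
}
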