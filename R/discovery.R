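#' Storey q-values
#'
#' The proportion of true nulls pi0 is estimated on the grid lambda = 0.05,
#' 0.10, ..., 0.95 as pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)),
#' smoothed with a cubic smoothing spline (df = 3) and evaluated at
#' lambda = 0.95, then clipped to (0, 1]. The q-value of hypothesis i is
#' pi0 * min over \{j : p_j >= p_i\} of p_j m / rank_j. With \code{pi0 = 1}
#' this is exactly Benjamini-Hochberg.
#'
#' @param p numeric p-values in (0, 1].
#' @param pi0 optional fixed pi0 (e.g. 1 for plain BH).
#' @return list with \code{q} (same order as \code{p}) and \code{pi0}.
#' @export
estimateQvalues <- function(p, pi0 = NULL) {
  p <- as.numeric(p)
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (m >= 100 && stats::var(pi0l) > 0) {
      sp <- stats::smooth.spline(lam, pi0l, df = 3)
      stats::predict(sp, x = max(lam))$y
    } else min(1, 2 * mean(p))  # small-m fallback: conservative moment rule
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(p[o] * m / rank(p, ties.method = "max")[o]))[ro]
  list(q = q, pi0 = pi0)
}

#' Select candidate SNP effects at a q-value threshold
#'
#' Computes q-values on the genomic-control adjusted p-values (direct and
#' indirect pooled separately), selects every effect with q strictly below
#' \code{qThr}, and records the implied per-test p threshold (the largest
#' passing GC-adjusted p), mirroring the "q < 0.3, corresponding to
#' p < ..." mapping. An empty selection is valid (the threshold is then
#' undefined, NA).
#'
#' @param scan a \linkS4class{ScanResult} after \code{\link{genomicControl}}.
#' @param qThr q-value threshold (default 0.3, a deliberately liberal FDR).
#' @param pi0 optional fixed pi0 passed to \code{\link{estimateQvalues}}.
#' @return list with \code{candidates} (data.frame: snp_id, effect, p, q),
#'   \code{pThreshold}, \code{scan} (the ScanResult with q columns filled),
#'   \code{pi0} (per effect type).
#' @export
selectCandidates <- function(scan, qThr = 0.3, pi0 = NULL) {
  tab <- scanTable(scan)
  if (all(is.na(tab$p_D_gc)))
    stop("run genomicControl() before selecting candidates")
  qd <- estimateQvalues(tab$p_D_gc, pi0 = pi0)
  qi <- estimateQvalues(tab$p_I_gc, pi0 = pi0)
  tab$q_D <- qd$q; tab$q_I <- qi$q
  cand <- rbind(
    data.frame(snp_id = tab$snp_id, effect = "direct",
               p = tab$p_D_gc, q = tab$q_D, stringsAsFactors = FALSE),
    data.frame(snp_id = tab$snp_id, effect = "indirect",
               p = tab$p_I_gc, q = tab$q_I, stringsAsFactors = FALSE))
  cand <- cand[cand$q < qThr, , drop = FALSE]
  pThr <- if (nrow(cand)) max(cand$p) else NA_real_
  list(candidates = cand[order(cand$p), , drop = FALSE], pThreshold = pThr,
       scan = new("ScanResult",
                  table = tab, model = scan@model, gc = scan@gc),
       pi0 = c(direct = qd$pi0, indirect = qi$pi0))
}

#' Backwards elimination of jointly fitted SNP effects
#'
#' All candidate direct and indirect effects are fitted jointly by GLS with
#' the covariance fixed at the null fit (direct and indirect effects
#' compete in the same model, accounting for LD between candidates). The
#' effect with the largest p-value above the implied threshold is dropped
#' and the model refitted, until every remaining effect passes. Ties on p
#' drop the smaller |effect| first; perfectly collinear candidates drop the
#' later-positioned one first. Allele substitution effects alpha are taken
#' from the final joint model and variance-explained accounting uses
#' \code{\link{varianceExplained}}.
#'
#' @param fit \linkS4class{NullModelFit} (STM) supplying the fixed
#'   covariance, sigma2_P and sigma2_A.
#' @param geno imputed \linkS4class{GenotypeMatrix}.
#' @param candidates data.frame with columns snp_id, effect
#'   ("direct"/"indirect"), q (from \code{\link{selectCandidates}}).
#' @param pThreshold the implied p threshold; effects with joint-model p
#'   strictly above it are eliminated (the boundary candidate that defines
#'   the threshold has, by construction, reached it).
#' @param cages \linkS4class{CageLayout} (default from the fit).
#' @return an \linkS4class{EliminationResult}.
#' @export
backwardEliminate <- function(fit, geno, candidates, pThreshold,
                              cages = NULL) {
  stopifnot(fit@model == "STM")
  ctx <- fit@engine$ctx
  if (is.null(cages)) cages <- ctx$cages
  if (!nrow(candidates))
    return(new("EliminationResult",
               retained = data.frame(), trace = data.frame(),
               pThreshold = NA_real_))
  stopifnot(is.finite(pThreshold))

  cv <- snpCovariates(geno, cages, ids = ctx$ids,
                      snps = unique(candidates$snp_id))
  C <- sapply(seq_len(nrow(candidates)), function(k) {
    if (candidates$effect[k] == "direct") cv$direct[, candidates$snp_id[k]]
    else cv$indirect[, candidates$snp_id[k]]
  })
  C <- matrix(C, ncol = nrow(candidates))
  colnames(C) <- paste(candidates$snp_id, candidates$effect, sep = ":")

  active <- seq_len(nrow(candidates))
  trace <- data.frame(step = integer(), snp_id = character(),
                      effect = character(), p = numeric(),
                      reason = character(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    g <- glsFixed(fit@engine, C[, active, drop = FALSE])
    if (any(!g$estimable)) {
      # collinear candidates: drop the later-positioned inestimable one
      drop_k <- max(which(!g$estimable))
      step <- step + 1L
      trace <- rbind(trace, data.frame(
        step = step, snp_id = candidates$snp_id[active[drop_k]],
        effect = candidates$effect[active[drop_k]], p = NA_real_,
        reason = "collinear", stringsAsFactors = FALSE))
      active <- active[-drop_k]
      if (!length(active)) break
      next
    }
    failing <- which(g$p > pThreshold)   # the boundary candidate passes
    if (!length(failing)) break
    pmax_ <- max(g$p[failing])
    worst <- failing[g$p[failing] == pmax_]
    if (length(worst) > 1)                    # tie: smaller |alpha| first
      worst <- worst[which.min(abs(g$beta[worst]))]
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, snp_id = candidates$snp_id[active[worst]],
      effect = candidates$effect[active[worst]], p = g$p[worst],
      reason = "above threshold", stringsAsFactors = FALSE))
    active <- active[-worst]
    if (!length(active)) break
  }

  if (!length(active))
    return(new("EliminationResult", retained = data.frame(), trace = trace,
               pThreshold = pThreshold))

  g <- glsFixed(fit@engine, C[, active, drop = FALSE])
  sigmaP2 <- fit@sigmaP2
  sigmaA2 <- unname(varComp(fit)["a"])
  maf <- mafs(geno)[candidates$snp_id[active]]
  pMajor <- pmax(maf, 1 - maf)
  alpha <- g$beta
  V <- varianceExplained(pMajor, alpha)
  prop <- explainedProportions(V, sigmaP2, sigmaA2)
  qv <- if ("q" %in% names(candidates)) candidates$q[active] else NA_real_
  retained <- data.frame(
    snp_id = candidates$snp_id[active], effect = candidates$effect[active],
    maf = unname(maf), p_major = unname(pMajor),
    alpha_days = alpha, se = g$se, p = g$p, q = qv,
    V_days2 = unname(V), pct_sigmaP2 = unname(prop$pctP),
    pct_sigmaA2 = unname(prop$pctA), stringsAsFactors = FALSE)
  new("EliminationResult", retained = retained, trace = trace,
      pThreshold = pThreshold)
}

#' Genetic variance explained by a SNP
#'
#' V = 2 p (1 - p) alpha^2 in days^2, where p is the major allele frequency
#' and alpha the allele substitution effect. The formula is symmetric in p
#' versus 1 - p, so allele-count orientation cannot change V.
#'
#' @param p major allele frequency in [0, 1] (vectorized).
#' @param alpha allele substitution effect in days.
#' @return V in days^2.
#' @export
varianceExplained <- function(p, alpha) {
  stopifnot(all(p >= 0 & p <= 1))
  2 * p * (1 - p) * alpha^2
}

#' Proportions of phenotypic and genetic variance explained
#'
#' @param V variance explained by the SNP (days^2).
#' @param sigmaP2,sigmaA2 phenotypic and total genetic variance (days^2).
#' @return list with \code{pctP} = 100 V / sigmaP2 and \code{pctA} =
#'   100 V / sigmaA2 (percent).
#' @export
explainedProportions <- function(V, sigmaP2, sigmaA2) {
  if (sigmaP2 <= 0 || sigmaA2 <= 0) stop("variance denominators must be > 0")
  list(pctP = 100 * V / sigmaP2, pctA = 100 * V / sigmaA2)
}
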