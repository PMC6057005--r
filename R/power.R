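#' Power specification for the cage design
#'
#' @param n number of phenotyped individuals.
#' @param sigmaP2 phenotypic variance (days^2).
#' @param cageSize cage size (5 in the study design).
#' @param rho correlation between cage mates' dosages; defaults to 0.25,
#'   the additive relationship of paternal half-sibs.
#' @param zThr significance threshold in standard-normal units (default 4,
#'   approximating the liberal q < 0.3 genome-wide threshold).
#' @param targetPower target detection probability.
#' @return validated list of class \code{PowerSpec}.
#' @export
PowerSpec <- function(n, sigmaP2, cageSize = 5L, rho = 0.25, zThr = 4,
                      targetPower = 0.8) {
  stopifnot(zThr > 0, targetPower > 0, targetPower < 1, rho >= 0, rho < 1,
            n > 0, sigmaP2 > 0, cageSize >= 2)
  structure(list(n = n, sigmaP2 = sigmaP2, cageSize = as.integer(cageSize),
                 rho = rho, zThr = zThr, targetPower = targetPower),
            class = "PowerSpec")
}

#' Standard error of a direct or indirect SNP effect
#'
#' Normal approximation: SE = sigma_P / sqrt(N var(x)). The direct
#' covariate has variance 2p(1-p); the indirect covariate (sum of n-1 cage
#' mates' dosages) has variance (n-1) 2p(1-p) (1 + (n-2) rho), which is the
#' source of the higher power for indirect effects.
#'
#' @param kind "direct" or "indirect".
#' @param spec a \code{\link{PowerSpec}}.
#' @param p allele frequency (vectorized).
#' @return SE in days (Inf at p = 0 or 1).
#' @export
effectSE <- function(kind = c("direct", "indirect"), spec, p) {
  kind <- match.arg(kind)
  vd <- 2 * p * (1 - p)
  v <- if (kind == "direct") vd
       else (spec$cageSize - 1) * vd * (1 + (spec$cageSize - 2) * spec$rho)
  se <- sqrt(spec$sigmaP2) / sqrt(spec$n * v)
  se[v <= 0] <- Inf
  se
}

#' Power to detect a SNP effect
#'
#' power = P(Z > z_thr - effect / SE) under the normal approximation; at
#' effect 0 this is the significance level itself.
#'
#' @param effect true effect size in days (>= 0, vectorized).
#' @param kind "direct" or "indirect".
#' @param spec a \code{\link{PowerSpec}}.
#' @param p allele frequency.
#' @return detection probability in [0, 1].
#' @export
powerAt <- function(effect, kind = c("direct", "indirect"), spec, p) {
  se <- effectSE(kind, spec, p)
  stats::pnorm(spec$zThr - effect / se, lower.tail = FALSE)
}

#' Minimum detectable effect
#'
#' effect* = (z_thr + z_power) SE, the smallest true effect detected with
#' the target power.
#'
#' @param kind "direct" or "indirect".
#' @param spec a \code{\link{PowerSpec}}.
#' @param p allele frequency.
#' @param targetPower target power (default from spec).
#' @return effect size in days.
#' @export
minDetectableEffect <- function(kind = c("direct", "indirect"), spec, p,
                                targetPower = spec$targetPower) {
  alpha <- stats::pnorm(spec$zThr, lower.tail = FALSE)
  stopifnot(targetPower > alpha, targetPower < 1)
  (spec$zThr + stats::qnorm(targetPower)) * effectSE(kind, spec, p)
}

#' Power grid over effect sizes and allele frequencies
#'
#' @param spec a \code{\link{PowerSpec}}.
#' @param effects effect grid in days.
#' @param freqs allele-frequency grid in (0, 1).
#' @return data.frame in long format: kind, effect, freq, power, plus the
#'   minimum detectable effect per frequency as attribute
#'   \code{"minDetectable"} (data.frame kind, freq, effect).
#' @export
powerGrid <- function(spec, effects = 1:18, freqs = seq(0.05, 0.95, 0.05)) {
  grid <- expand.grid(kind = c("direct", "indirect"), effect = effects,
                      freq = freqs, stringsAsFactors = FALSE)
  grid$power <- mapply(function(k, e, f) powerAt(e, k, spec, f),
                       grid$kind, grid$effect, grid$freq)
  md <- expand.grid(kind = c("direct", "indirect"), freq = freqs,
                    stringsAsFactors = FALSE)
  md$effect <- mapply(function(k, f) minDetectableEffect(k, spec, f),
                      md$kind, md$freq)
  attr(grid, "minDetectable") <- md
  grid
}
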