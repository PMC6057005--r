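---
title: "Mixed-model GWAS for direct and indirect genetic effects on survival in group-housed animals"
author: "sgeGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model GWAS for direct and indirect genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In group-housed laying hens with intact beaks, mortality is driven largely
by cannibalism. Survival time is then a *socially affected* trait: a hen's
survival depends on her own genotype (direct genetic effects, DGE) and on
the genotypes of her cage mates (indirect or social genetic effects, IGE).
sgeGWAS implements a complete association pipeline for this setting: data
simulation under the half-sib cage design, genotype quality control,
pedigree-based mixed-model null fits, a simultaneous direct + indirect SNP
scan under three models, genomic control, q-value FDR, backwards
elimination with variance-explained accounting, and closed-form power.

## The models

**Survival-time model (STM).** For hen $i$ in cage $k$,

$$y_{ik} = \text{location} + \beta_D\,x_i + \beta_I \sum_{j \ne i} x_{j(k)}
 + a_i + c_k + e_{ik},$$

where $y_{ik}$ is survival time in days (censored records are set to the
402-day recording period), $x_i \in \{0,1,2\}$ is the allele count (0–8 for
the cage-mate sum with cages of five), $a$ is a polygenic effect with
$\mathrm{var}(a) = \mathbf{A}\sigma^2_a$ for the pedigree relationship
matrix $\mathbf{A}$, $c_k \sim (0, \sigma^2_{cage})$ and
$e \sim (0, \sigma^2_e)$. Because cage mates are paternal half- or
full-sibs, direct and indirect *polygenic* effects are confounded, and a
DGE-only animal model picks up the total heritable variance; $T^2 =
\sigma^2_a/\sigma^2_P$ is therefore a total-heritability ratio, not a
narrow-sense direct one. The polygenic term also controls the family
stratification that would otherwise inflate SNP associations.

**Repeated-measures random-regression model (RMM.t).** The 402-day period
is split into 13 equal months (boundary of month $m$ at
$\mathrm{round}(402m/13)$ days); the monthly record is 1 while the hen is
alive at the boundary and 0 afterwards, giving every hen 13 records. The
model adds random regressions on time $t_m = 1..13$: genetic slope
$a_i t_m$, permanent-environment slope $PE_i t_m$, permanent cage slope
$c_k t_m$, a cage-by-month effect $c_{km}$, a fixed location-specific
sixth-order polynomial of time, and a separate residual variance per month.
SNP covariates enter multiplied by $t_m$, so the scan effects are per-month
slopes.

**Logit GLMM.** A binomial model with logit link on the same monthly
records, with random polygenic intercept, cage-by-month and
permanent-environment effects and the location-by-time fixed polynomial;
no genetic regression on time, because the non-linear link already lets
the variance of survival probabilities change over time. It is fitted by
penalized quasi-likelihood (PQL): working variates
$z = \eta + (y-\mu)/(\mu(1-\mu))$ with weights $\mu(1-\mu)$ are iterated
against REML fits of the linearized model. PQL hypothesis testing on
binary data is approximate and inherits the usual caveats; we treat the
GLMM as a cross-check on the two linear models.

## Estimation

Null-model variance components are estimated by REML without SNP effects.
The likelihood is evaluated through the sparse bordered mixed-model
equations $C = [X\,Z]'R^{-1}[X\,Z] + \mathrm{blkdiag}(0,
G_i^{-1}/\sigma^2_i)$ using the identity
$-2\ell_R = \log|R| + \log|G| + \log|C| + y'Py$; each evaluation is one
cached-pattern sparse Cholesky factorization plus one solve, with the
matrix assembled through precomputed index maps into a fixed sparsity
template. The criterion is maximized directly over log-variances with
L-BFGS-B, profiling the residual variance out when it is homoscedastic.
We chose direct maximization over average-information updates because the
AI algorithm's trace terms require selected sparse inversion that the
Matrix package does not expose, while quasi-Newton on the profiled
criterion is robust at variance bounds and converges in tens of
evaluations at milliseconds each. Components are bounded below at
$10^{-8}\,\mathrm{var}(y)$; convergence is controlled to about $10^{-7}$
on the $-2\ell$ scale. Asymptotic standard errors come from the
finite-difference observed information of the log-variances (delta
method); they are off by default for the 17-parameter RMM.t fit, where the
Hessian costs more than the fit itself.

The SNP scan fixes all variance components at the null estimates and fits
the direct and indirect covariates *simultaneously* as fixed effects by
generalized least squares — fitting the direct effect alone would absorb
part of the indirect effect, because related cage mates share alleles. The
null fit's single sparse factorization is reused for every SNP through the
Schur complement of the bordered system, and per-SNP work is two sparse
triangular solves. Each effect is tested with a 1-df Wald chi-square
(Wald F tests with estimated denominator degrees of freedom, as reported
by REML packages of the ASReml class, are asymptotically equivalent; the
chi-square makes the scan deterministic and is our documented choice). Monomorphic or collinear covariates are flagged
not-estimable with $p = 1$.

**Genomic control.** $\lambda = \mathrm{median}(\text{Wald})/0.4549$,
separately for direct and indirect statistics; when $\lambda > 1.10$
(strictly) statistics are divided by $\lambda$ before p-values are
recomputed, and the q-value step runs on the GC-adjusted p-values.

**FDR and backwards elimination.** Storey q-values with the smoother
$\hat\pi_0(\lambda)$ on the grid $0.05..0.95$ (df-3 smoothing spline,
evaluated at 0.95, clipped to $(0,1]$); with $\pi_0 = 1$ the procedure is
exactly Benjamini–Hochberg, which the tests assert against
`p.adjust`. For small inputs (< 100 p-values) the smoother is unstable and
a conservative moment rule $\min(1, 2\bar p)$ is used instead. All direct
and indirect effects with $q < 0.3$ — a deliberately liberal threshold for
a first large study of these traits — enter one joint GLS model; the
implied per-test threshold is the largest passing GC-adjusted p-value, and
the effect with the largest joint p-value strictly above it is dropped
iteratively (ties drop the smaller $|\alpha|$; perfectly collinear
candidates drop the later-positioned one) until all remaining effects
pass. For each retained effect, $V = 2p(1-p)\alpha^2$ with $p$ the major
allele frequency, reported as percentages of $\sigma^2_P$ and
$\sigma^2_A$. Because selection precedes estimation, retained effects are
upward-biased (the Beavis effect) and summed $V/\sigma^2_A$ may exceed
100%; the package reports, and does not cap, such values.

**Power.** Under a normal approximation,
$\mathrm{SE} = \sigma_P/\sqrt{N\,\mathrm{var}(x)}$ with
$\mathrm{var}(x_{direct}) = 2p(1-p)$ and $\mathrm{var}(x_{indirect}) =
(n-1)\,2p(1-p)\,(1+(n-2)\rho)$ for cage size $n$ and cage-mate dosage
correlation $\rho$ (default 0.25, the additive relationship of paternal
half-sibs). Power is $P(Z > z_{thr} - \beta/\mathrm{SE})$ with $z_{thr} =
4$ approximating the $q<0.3$ genome-wide threshold, and the minimum
detectable effect is $(z_{thr}+z_{power})\,\mathrm{SE}$. Using $\sigma_P$
rather than the residual SD is conservative. With the three crosses'
$(N, \sigma^2_P)$ this reproduces the qualitative orderings — indirect
effects are detectable at roughly half to a quarter of the direct effect
size, and the smallest cross has the least power — and gives about 13.7
days for the direct minimum detectable effect in the largest cross; the
published figure (15 days) rests on a supplementary derivation that is not
part of the main text, and we report our closed form rather than
reconciling the difference.

## The synthetic-data generator

`SimConfig()` defaults encode the design of one crossbred layer line: 48
sires × 20 dams × 2 female offspring (1,920 hens), single-sire cages of
five (half- or full-sibs), 24 wing-row-level location classes with fixed
effects on an even ±10-day grid, ~30,000 unlinked biallelic SNPs with
founder frequencies uniform on [0.01, 0.5], gene-dropped through the
pedigree under Hardy–Weinberg and fair Mendelian sampling, 4% genotype
missingness, and survival-time variance components
$\sigma^2_a = 576$, $\sigma^2_{cage} = 763$, $\sigma^2_e = 6306$ days²
($\sigma^2_P = 7645$). Polygenic values follow parental averages with
Mendelian-sampling variance $\sigma^2_a/2$, so $\mathrm{var}(a) =
\mathbf{A}\sigma^2_a$. Latent survival is the linear model's sum, clipped
to $[1, 402]$, rounded to whole days, and censored at the cap; QTL effects
enter exactly in the covariate form the scan estimates, so scan estimands
equal generative parameters. SNPs are simulated without linkage
disequilibrium — LD in the real data is an observed property, not needed
to test the machinery — and a config switch duplicates QTL columns to
create perfect-LD pairs for elimination tests.

What the generator does *not* emulate: genotyping error, real LD
structure, sex chromosomes, pedigree errors, and — importantly — the shape
of the real survival distribution. A clipped Gaussian at the observed mean
(365 d) and SD (87 d) reproduces the first two moments of survival time
but concentrates deaths late: no simulated hen dies in the first months,
whereas the real cohorts lost hens in every month. Three regimes are
therefore used deliberately in the tests and the acceptance script:

* **default** (`baseline_mean = 365`, censoring at 402): the study-scale
  regime for QC, null calibration and bookkeeping checks;
* **latent** (`baseline_mean = 402`, `censor_day = 2000`): no record is
  clipped, the linear model is exactly correct, and estimator-recovery
  experiments (the 22-day allele-substitution effect, REML component
  recovery, elimination truth-recovery) measure bias without censoring
  attenuation — under heavy censoring the linear-model estimand of a
  latent effect is attenuated and recovery would measure the censoring,
  not the estimator;
* **all-months-informative** (`baseline_mean = 256`): mortality occurs in
  every month, so all 13 monthly records carry contrasts; used for the
  STM-versus-RMM.t agreement experiment, which is meaningless when most
  monthly records are constant.

Passing tests under these regimes show the estimators and their fast
paths are correct under the model's own assumptions at the study's scale;
they do not show robustness to the real data's skewed survival
distribution, LD, or pedigree errors.

## Numerical choices and degenerate inputs

* Threshold comparisons in QC are strict (`> 0.30`, `< 0.005`, `> 0.10`,
  `< 1e-5`), matching "higher/lower than" wording; a SNP at MAF exactly
  0.005 is kept. MAF is computed in the analyzed individuals.
* Hardy–Weinberg uses the 1-df chi-square goodness of fit in the parental
  population (deterministic; no exact test). Monomorphic SNPs get
  $\chi^2 = 0$ and are left to the MAF filter.
* Parental-mean imputation: missing dosage ← (sire + mean of the sire's
  mates)/2, mates being dams with at least one offspring by that sire;
  line mean $2\hat p$ as fallback. Only observed calls feed an
  imputation — an imputed parent does not cascade into its offspring's
  imputation. Imputed fractional dosages flow into cage-mate sums, which
  keeps cages with non-genotyped members usable.
* Months in which no hen died have zero record variance and an unbounded
  REML likelihood; `fitNullRMM`/`fitNullGLMM` drop such months with a
  message, and remaining month residual variances are floored at $10^{-3}$
  (record scale) so near-constant months cannot acquire effectively
  infinite GLS weight.
* PQL clamps fitted probabilities to $[10^{-6}, 1-10^{-6}]$ under
  separation and reports the clamp count.
* A monomorphic or collinear SNP covariate is reported not-estimable
  ($p = 1$) rather than dropped silently.
* All randomness flows from a single integer seed per simulated dataset;
  identical seeds give bitwise-identical datasets.

## Problem sizes used by the tests and the acceptance script

Unit tests run on populations of 100–400 hens with tens of SNPs. The
acceptance script and the acceptance tests use the full design (1,920
hens): 200 replicates with a 40-SNP panel for the allele-substitution
recovery, one 500-SNP dataset for the STM/RMM.t agreement, and a 24-sire,
400-SNP dataset for null calibration — panel sizes chosen because the
measured quantities (a single SNP's estimate; a correlation over SNPs; a
median statistic) are insensitive to panel width once the design is at
full scale.

## Known limitations

* DGE and IGE polygenic components are not separated (they are confounded
  in family-structured cages by design); $\sigma^2_a$ is total heritable
  variance.
* PQL variance components for binary monotone records are biased (the
  monthly records of one hen are a deterministic step function, and the
  permanent-environment variance absorbs this); the GLMM is a
  cross-check, not the primary model.
* The power module's normal approximation ignores relatedness beyond the
  cage-mate dosage correlation and uses $\sigma_P$ conservatively.
* The elimination procedure at $q < 0.3$ admits false candidates at the
  rate the FDR definition implies; exact recovery of a causal set is not
  a property the procedure can guarantee.
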