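---
title: "Two-step mediation Mendelian randomization: models, defaults and design choices"
author: "mrMediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mediation Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrMediate)
```

# The scientific problem

Serum urate is epidemiologically associated with atrial fibrillation, but
observational associations cannot separate causation from confounding.
Two-sample Mendelian randomization (MR) uses genetic variants as
instruments: a SNP that raises urate is allocated at conception,
independent of lifestyle confounders, so if urate causes atrial
fibrillation, urate-raising alleles must also raise atrial-fibrillation
risk. mrMediate implements the full analysis chain for this design and
its mediation extension, in which the causal path is decomposed through
plasma proteins: a first MR leg from exposure to each candidate protein,
a second leg from the protein to the outcome, and a product-of-
coefficients decomposition of the total effect.

All computation happens on GWAS summary statistics: per-SNP effect
estimates $\hat\gamma_j$ (exposure) and $\hat\Gamma_j$ (outcome) with
standard errors $\sigma_{xj}, \sigma_{yj}$, on the log-odds scale for
binary traits.

# Instrument selection

The selection chain runs in a fixed order, each step recorded in a
telescoping `FilterLedger`:

1. **p-value threshold** — strict $p < 5\times10^{-8}$ for the exposure;
   $p < 1\times10^{-5}$ for protein legs, where genome-wide instruments
   are often too few and the relaxed threshold trades heterogeneity
   against explained variance.
2. **Clumping** — greedy by ascending p-value; a candidate is rejected if
   an accepted SNP on the same chromosome lies within 10,000 kb with
   $r^2 \ge 0.001$. Without an LD matrix the rule degrades to pure
   distance pruning and says so loudly; no LD reference panel ships with
   the package. Ties break on (p-value, SNP id), making the result
   independent of input order.
3. **Harmonization** — intersection by SNP id; palindromic (A/T, C/G)
   pairs are removed unconditionally (an opt-in frequency rescue with
   $|\mathrm{eaf}-0.5| > 0.08$ exists but defaults off, because strand
   cannot be resolved from alleles alone); allele sets that fail to match
   even after strand complementing are ambiguous and removed; otherwise
   the outcome effect is sign-flipped onto the exposure's effect allele.
4. **Weak instruments** — per-SNP $F = (\hat\gamma/\sigma_x)^2$; SNPs
   with $F < 10$ are removed (inclusive at 10: removal is for $F$
   *below* 10). The exact form $(n-2)R^2/(1-R^2)$ with
   $R^2 = 2\,\mathrm{eaf}(1-\mathrm{eaf})\hat\gamma^2$ is available when
   frequency and sample size are present; the $(\hat\gamma/\sigma_x)^2$
   approximation is the default because per-study $R^2$ is usually not
   published.
5. **MR-PRESSO outliers**, 6. **Steiger direction filter**,
   7. **confounder blacklist** (a local annotation table standing in for
   phenome-wide lookups; the confounder patterns are user
   configuration), 8. **outcome-association Bonferroni screen**
   ($p_\mathrm{out} < \alpha/k$ removes SNPs that plausibly violate the
   exclusion restriction).

# Estimators

With Wald ratios $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ and
first-order weights $w_j = \hat\gamma_j^2/\sigma_{yj}^2$:

* **IVW**: $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$. Fixed-effect SE
  $(\sum w_j)^{-1/2}$; the random-effects (multiplicative) SE inflates by
  $\max(1, \sqrt{Q/(k-1)})$ and can never undercut the fixed SE. A
  single instrument delegates to the Wald ratio. Second-order ratio
  weights (adding the $\hat\Gamma^2\sigma_x^2/\hat\gamma^4$ term) are a
  configuration switch; first-order is the default, matching standard
  IVW practice.
* **MR-Egger**: weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$
  with free intercept (the average directional pleiotropic effect),
  weights $1/\sigma_{yj}^2$, after orienting all $\hat\gamma_j \ge 0$ —
  the identifiability convention for the intercept. Coefficient SEs are
  scaled by $\max(1,\sqrt{RSS_w/(k-2)})$. The NOME diagnostic
  $I^2_{GX} = (Q_{GX}-(k-1))/Q_{GX}$ (floored at 0) warns below 0.9,
  where regression dilution attenuates the slope.
* **Weighted median**: the ratio at which the cumulative normalized
  weight crosses one half, linearly interpolated; consistent while at
  least half the weight is valid. SE by seeded parametric bootstrap.
* **Mode estimators**: Gaussian-kernel density over the ratios with the
  modified Silverman bandwidth
  $h = \phi\,0.9\,\min(sd, \mathrm{MAD}/0.6745)\,k^{-1/5}$, maximized on
  a 512-point grid spanning the ratio range $\pm 3h$; both $\phi$ and the
  grid resolution are exposed. All-identical ratios short-circuit to the
  common value with the IVW SE.
* **RAPS** (robust adjusted profile score): pleiotropy modelled as a
  mean-zero random effect with variance $\tau^2$. With standardized
  residuals
  $t_j = (\hat\Gamma_j - \beta\hat\gamma_j)/\sqrt{\sigma_{yj}^2 + \beta^2\sigma_{xj}^2 + \tau^2}$,
  the slope solves $\sum \psi_c(t_j)\,\partial t_j/\partial\beta = 0$
  (Huber $\psi$, $c = 1.345$; Tukey available) and $\tau^2$ solves
  $\sum \psi_c(t_j)\,t_j = (k-1)\,\delta_c$ with
  $\delta_c = E[\psi_c(Z)Z] = 2\Phi(c)-1$ the reference expectation that
  makes the equation unbiased under normality. The $(k-1)$ multiplier is
  a small-sample degrees-of-freedom adjustment for the estimated slope,
  by analogy with the unbiased residual variance; without it $\tau^2$ is
  biased low by roughly one part in $k$. The solver is deterministic
  (profiled $\tau^2$ by bisection inside a bracketed root search for
  $\beta$), so RAPS results are exactly reproducible without a seed. The
  SE uses the expectation-form sandwich
  $E[\psi^2]/(E[\psi']^2\sum d_j^2)$, which stays positive even on
  zero-residual data.

P-values are two-sided normal everywhere (chi-square for Q); the
$p < 0.05$ significance rule is applied by the pipeline, never inside
estimators.

# Diagnostics

* **MR-PRESSO**: observed residual sum of squares around leave-one-out
  IVW predictions, compared against a simulated null in which both sides
  are redrawn from their sampling distributions and the leave-one-out
  slopes recomputed per draw. The add-one pseudo-count makes the global
  p strictly positive and super-uniform at resolution $1/(n_{sim}+1)$.
  Per-SNP outlier p-values are Bonferroni-adjusted by $k$ — note this
  means $n_{sim}$ must exceed roughly $k/\alpha$ before any SNP *can* be
  flagged; the default $n_{sim} = 1000$ suffices for $k \le 50$ at
  $\alpha = 0.05$. The distortion test locates the all-SNP estimate in a
  bootstrap distribution of the outlier-free estimate.
* **Steiger**: per-SNP variance explained $r^2 = z^2/(z^2+n-2)$; for the
  binary outcome the correlation is first formed on the observed scale,
  $r = \hat\Gamma\sqrt{2\,\mathrm{eaf}(1-\mathrm{eaf})}\sqrt{cf(1-cf)}$,
  then squared (the z-based form is the documented fallback when
  frequencies are missing). The overall test is a two-sided z test on
  the difference of Fisher-transformed total correlations — the two
  cohorts are independent, so no dependent-correlation correction is
  needed. The filter drops SNPs with $r^2_{out} > r^2_{exp}$ and can
  never remove anything when outcome effects vanish.
* **Power**: the closed normal approximation
  $\Phi(|\ln OR|\sqrt{n\,R^2\,cf(1-cf)} - z_{1-\alpha/2})$, cross-checked
  in the tests against numeric quadrature of the same tail.

# Decision rules

The pipeline applies the conventional hierarchy: if the Egger intercept
is significant, directional pleiotropy is declared and MR-Egger becomes
the principal estimate; otherwise random-effects IVW is principal, with
the weighted median emphasized when Cochran's Q is significant. Because
the intercept test has its nominal false-positive rate, about 5% of
pleiotropy-free runs will switch to Egger — the tests therefore assert
the rule's majority behaviour over seeds, not a single draw.

# Mediation

On the log-odds scale: indirect $= \beta_1\beta_2$, SE by the delta
method $\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$ (the exact-variance
term $se_1^2 se_2^2$ is a switch); direct $=$ total $-$ indirect, so the
decomposition is exact by construction; proportion $=$
indirect/total. Classification: *partial* when both steps and the total
are significant, *complete* when both steps are but the total is not,
*none* otherwise. Step-2 MR is run only for step-1-significant mediators
(the others are classified none without a step-2 estimate), and the
step-1 screen uses unadjusted $\alpha = 0.05$ by default with BH-FDR as
an option. Step-2 estimates are univariable, not exposure-adjusted.

The reporting convention deserves a note: published tables of this
design print the *raw fraction* indirect/total followed by a percent
sign (e.g. 0.0066/0.0440 = 0.149 printed as "0.15%"). The package
returns the raw fraction and formats the label exactly as printed,
surfacing rather than silently resolving the discrepancy. A bootstrap
percentile interval for the proportion is available
(`proportionCI()`), since no analytic interval is standard.

# The synthetic generator

`simConfig()`/`simulateMediationGwas()` encode the causal diagram of the
two-step design with the conservation identity
$\theta_{total} = \theta_{direct} + \sum_k \beta_{1k}\beta_{2k}$
enforced at construction ($\theta_{direct}$ is always derived).

Key design choices, fixed once:

* **Cohort sizes** follow the three study cohorts: a continuous exposure
  GWAS of 110,347; protein GWAS of 3,301; a binary outcome GWAS of
  1,030,836 with case fraction 60620/1030836. Binary-trait SEs use the
  log-OR approximation with effective $n = n\,cf(1-cf)$; all SEs are
  $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n_{eff}}$.
* **Desk scale**: 100 exposure-instrument SNPs and 5 mediators with 30
  cis instruments each — not the hundreds of thousands of SNPs and
  thousands of proteins of the real assay; the generator emulates the
  sampling structure, not the genome. Simulations in the tests use
  these sizes (30–100 SNPs, 100–200 replicates), chosen so the whole
  suite completes in well under a minute while Monte-Carlo error stays
  far below the asserted tolerances.
* **Mediators carry their own cis instruments** (effect SD 0.3),
  independent of the exposure instruments. This is both biologically
  faithful (protein levels have strong cis-pQTLs) and statistically
  necessary: a step-2 leg run on exposure instruments would identify
  $\theta_{total}/\beta_1$, not $\beta_2$.
* **Exposure instrument effects** are drawn with SD 0.1 per allele —
  urate-like loci have unusually large effects — which gives the
  step-1 leg realistic power at the small protein-GWAS sample size.
* **Pleiotropic offsets are oriented to the exposure-increasing
  allele**, the MR-Egger convention; unoriented offsets would cancel in
  the intercept regardless of their mean.
* **LD blocks** duplicate a causal signal at tightly packed positions
  with correlated noise ($\sqrt{r^2}$-shared component) — enough to
  exercise clumping, not a realistic recombination map.
* **Palindromic fraction** defaults to 0.05; alleles are otherwise drawn
  uniformly from the non-palindromic ordered pairs.

What passing tests on this generator do *not* show: robustness to
sample overlap between cohorts (the two-sample independence assumption
is hard-wired), realistic LD structure, assay measurement error beyond
sampling noise, or selection effects in published GWAS. Conclusions
about real data still require the diagnostics battery.

# Numerical choices

* Strict "<" at every p-value threshold; inclusive "$\ge$" at the F
  cutoff.
* Input p-values of exactly 0 are clamped to the smallest positive
  double with a warning; missing p-values are imputed from the normal z
  approximation; |z| vs p inconsistencies beyond a tolerance warn but do
  not drop rows.
* The weighted-median/mode bootstrap and every simulation are seeded;
  identical seeds give bit-identical output, and `runAll()` directories
  are byte-identical under a fixed seed.
* RAPS brackets its root around the IVW estimate and expands the
  bracket geometrically before declaring non-convergence.
* Degenerate inputs have defined behaviour: all-identical ratios (mode
  short-circuit), zero exposure effect (Wald error), constant exposure
  effects (Egger declares the slope unidentifiable), empty funnel input
  (empty table).

# Known limitations

No multivariable MR (so no exposure-adjusted step-2 and no
MVMR-based mediation), no correlated-instrument IVW, no proxy-SNP
search, no reference-panel LD computation, and entity-level
overrepresentation only (pathway-topology "reactions found" counts are
out of scope). The enrichment universe defaults to all genes in the
loaded collection; supplying the assayed-protein universe is
recommended and changes p-values materially.
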