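---
title: "Two-sample Mendelian randomization with mrpipe: models, choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure. For SNP $j$, let $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) be its estimated per-allele effect on the exposure in one
GWAS and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its effect on the outcome in a
second, non-overlapping GWAS. If SNP $j$ is a valid instrument — associated
with the exposure, independent of confounders, and affecting the outcome
only through the exposure — then its Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$, with first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$, estimates the causal effect $\theta$. With
a binary outcome the effects are log-odds ratios, so $e^\theta$ is reported
as an odds ratio per SD of exposure.

The estimators combine the ratios under progressively weaker validity
assumptions:

* **IVW** — inverse-variance-weighted mean of the ratios, equal to the
  no-intercept weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ with
  weights $\sigma_Y^{-2}$. Unbiased only if *all* instruments are valid.
  The fixed-effects SE is $(\sum w_j)^{-1/2}$; when Cochran's
  $Q=\sum_j w_j(\hat\theta_j-\hat\theta)^2$ has $p<0.05$ the SE is scaled
  by $\sqrt{Q/(k-1)}$ (multiplicative random effects), which leaves the
  point estimate unchanged.
* **MR-Egger** — the same regression *with* an intercept, each instrument
  first oriented so $\hat\beta_X \ge 0$. Under InSIDE (pleiotropic effects
  independent of instrument strength) the slope stays consistent for
  $\theta$ while the intercept estimates the average directional
  pleiotropic effect. Inference uses $t_{k-2}$ with the residual dispersion
  floored at 1.
* **Weighted median** — interpolated median of the ratio distribution under
  cumulative standardized weights; consistent while valid instruments carry
  more than half the weight.
* **Simple/weighted mode** — argmax of a Gaussian kernel density over the
  ratios (unit or inverse-variance weights); consistent when the largest
  cluster of agreeing instruments is valid.

Sensitivity analysis asks whether any of this can be trusted: Cochran's Q
for heterogeneity, the Egger intercept for directional pleiotropy,
MR-PRESSO for individual outlier instruments, and leave-one-out for
single-SNP leverage.

## Instrument selection parameters

| parameter | default | rationale |
|---|---|---|
| `p_threshold` | 1e-5 | taxon-abundance GWAS rarely reach 5e-8; the relaxed threshold is the accepted trade-off for having instruments at all, at the cost of winner's-curse attenuation (below) |
| `clump_window_kb` | 10,000 kb | variants further apart are treated as independent |
| `clump_r2` | 0.01 | pairs at or above this r² are pruned, keeping the smaller p (ties broken by ascending rsID for determinism) |
| `f_min` | 10 | conventional weak-instrument floor, applied per SNP (k = 1 in the F formula); the set-level F from the summed R² is reported separately on the instrument set |
| `confounder_blacklist` | empty | rsIDs known to associate with confounder traits; supplied by the user — the package does not query trait catalogues |

LD is taken as an explicit user-supplied pair table; pairs absent from it
are treated as unlinked (r² = 0). This keeps clumping deterministic and
reference-panel-agnostic: with a curated panel table the behaviour matches
standard clumping, and with no table it degrades to the distance rule
alone. Minor-allele frequencies are folded (`pmin(eaf, 1-eaf)`) before the
R² formula.

Harmonization excludes palindromic (A/T, C/G) SNPs unconditionally — no
frequency-window rescue — because with two independent consortia strand
cannot be resolved reliably at intermediate frequencies, and the cost of a
blanket rule is a modest loss of instruments. Records are otherwise assumed
forward-strand: alleles must match directly or swapped, anything else is
excluded as incompatible. The blacklist is applied as the final single
pass, mirroring a scan-then-recalculate workflow while keeping selection a
deterministic function of its inputs.

## Numerical choices

* Median and mode SEs come from a parametric bootstrap (default 1000
  draws, seeded): each ratio is redrawn from
  $N(\hat\theta_j, \hat\sigma_{\theta j})$ with weights held fixed, and the
  SE is the SD of the recomputed estimates. P-values for these estimators
  use the normal approximation.
* The mode bandwidth is the modified Silverman rule
  $h = \phi\,0.9\min(\mathrm{sd}, \mathrm{IQR}/1.349)k^{-1/5}$ with
  $\phi = 1$; the density is evaluated on a 512-point grid spanning
  $[\min-3h, \max+3h]$ (both configurable). If all ratios coincide the
  common value is returned directly.
* MR-PRESSO simulates its null by redrawing both exposure and outcome betas
  around leave-one-out fitted values with the observed SEs (1000
  simulations by default), uses the add-one p estimator so p is never 0,
  and Bonferroni-corrects the per-SNP outlier tests by k. The distortion
  test is implemented but off by default. Outcome-side weights
  ($\sigma_Y^{-2}$) are used throughout this test.
* All stochastic components take explicit seeds and restore the caller's
  RNG state; pipeline runs derive per-exposure seeds from one base seed,
  so a rerun is byte-identical.
* Estimators requiring more instruments than available (Egger, median,
  mode need 3; MR-PRESSO needs 4) signal a typed condition that the
  pipeline converts into an `insufficient_instruments` row rather than a
  failure, and an exposure with zero surviving instruments is skipped, not
  fatal.

## What the synthetic generator emulates

`generate_summary_stats()` draws $k$ unlinked biallelic SNPs with MAF
uniform on [0.05, 0.5], true exposure effects
$\gamma_j \sim N(0, \texttt{gamma\_sd}^2)$ on a standardized scale, and
observed effects with the standard GWAS sampling SE
$(2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$. Defaults mirror the
motivating study design: exposure $n = 18{,}340$; outcome 240 cases and
456,108 controls.

Two generator choices deserve explanation:

* **Binary-outcome SE.** The sampling variance of a log-odds estimate under
  extreme case–control imbalance is governed by the *effective* sample size
  $n_\mathrm{eff} = 4/(1/n_\mathrm{cases}+1/n_\mathrm{controls})$ (~958
  here), not the total n of 456,348. Using total n would produce per-SNP
  outcome SEs ~0.002 — incompatible with the CI widths any 240-case GWAS
  can deliver — and would manufacture spurious heterogeneity whenever
  $\theta \ne 0$. The written outcome table still reports total n, as real
  files do. With this choice, k = 8 instruments give an IVW SE of ~0.3 on
  the log-odds scale, matching the reported CI widths for the
  microbiome–IC associations.
* **Directional pleiotropy in the oriented frame.** Directional means "the
  direct effects push the outcome one way for exposure-increasing
  alleles". Because each $\gamma_j$ is symmetric around zero, adding
  $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ in the *natural* frame
  would cancel on average ($E[\gamma\alpha]=0$) and bias nothing. The
  generator therefore applies
  $\alpha_j = \mathrm{sign}(\gamma_j)\,N(\mu_\alpha, \sigma_\alpha^2)$: in
  the exposure-increasing orientation — the frame MR-Egger fits in — the
  direct effects have constant mean $\mu_\alpha$, independent of
  instrument strength, so InSIDE holds there, IVW is biased, and the Egger
  slope remains consistent. Balanced pleiotropy uses the natural frame
  ($\mu=0$, symmetric, nothing to orient).

`gamma_sd` defaults to 0.08: with the exposure n this yields per-SNP F
values spanning roughly 15–90 (the range reported for real taxon
instruments) and a realistic yield of p < 1e-5 discoveries. Injected
outliers replace a SNP's direct effect with a stated multiple (default 10)
of its outcome SE, and are never drawn palindromic so they survive
harmonization and stay visible to the diagnostics. A 10% palindrome
fraction (default) exercises the harmonization drop path; a random half of
outcome records are written allele-swapped to exercise alignment.

The generator does **not** emulate: LD between instruments (clumping is
exercised by constructed examples with explicit LD tables), sample overlap
between the two GWAS, allele-frequency differences between cohorts,
winner's-curse selection in the *exposure discovery* GWAS (our p-filter
induces it on generated data, which is real attenuation, but the MiBioGen
effect sizes are themselves post-discovery), fine-mapped vs tag-SNP
distinctions, or compositionality of 16S relative abundances. Passing
recovery tests therefore demonstrates estimator correctness under the
stated sampling model, not robustness to everything real microbiome GWAS
data can do.

## Validation experiments and their sizes

The test suite and `scripts/acceptance.R` run these experiments (sizes are
the package's choices, balancing Monte-Carlo error against runtime):

* *Headline recovery*: true OR 2.20, k = 8, 300 replicates through
  selection + IVW; the recovered mean OR re-centres on the truth up to
  first-order attenuation (~0.02 log-odds at this strength).
* *Calibration*: θ = 0.5, k = 30 — 2000 replicates for mean bias and 95%
  CI coverage (2000 keeps the MCSE of the mean bias near 0.003, well
  below the 0.02 bias bound being checked); 1000 replicates for type-I
  error at θ = 0.
* *Pleiotropy separation*: μα = 0.1, 300 replicates; Egger slope vs IVW.
  Run at strong instrument strength (`gamma_sd = 0.3`) so orientation by
  `sign(beta_exposure)` is essentially error-free (see limitations).
* *MR-PRESSO*: 100 replicates of a single 10-SE outlier (detection rate);
  200 null replicates for approximate uniformity of the global p.
* *Oracles*: IVW vs no-intercept WLS and Egger vs with-intercept WLS at
  1e-10 on 100 random instances; weighted median vs an exhaustive
  interpolation oracle; Cochran's Q against the hand-computed value 5.0
  on ratios {0.5, 1.0} with SEs {0.2, 0.1}.

## Known limitations

* **Weak-instrument (NOME) attenuation.** First-order Wald-ratio SEs ignore
  exposure-side sampling error. At the default instrument strength this
  attenuates IVW towards the null by about 1.3% relative (measured mean
  bias ≈ −0.013 at θ = 0.5) — small against the sampling SE, but real.
* **Egger orientation error.** Orienting by the *estimated* exposure-effect
  sign misflips instruments whose true effect is near zero. Those misflips
  sit at small $|\hat\beta_X|$, exactly where the intercept is identified,
  attenuating the mean intercept (≈0.076 for a true 0.1 at default
  strength) and inflating the slope under directional pleiotropy. With
  strong instruments the orientation is error-free and both are recovered.
  This is a property of every sign-oriented Egger analysis, not of this
  implementation; it is why the pleiotropy-separation experiment runs at
  high instrument strength, and why real-data Egger intercepts from weak
  instrument sets should be read as lower bounds on directional pleiotropy.
* **MR-PRESSO null calibration.** The global p is built from plug-in
  leave-one-out slopes; their estimation noise inflates the simulated null
  RSS slightly, so the global p skews conservative (towards 1) at small k.
  Detection of genuine outliers is unaffected in our experiments (≥97%
  for 10-SE outliers at k = 10).
* **Winner's curse.** Selecting instruments at p < 1e-5 in the same data
  that provide $\hat\beta_X$ inflates the selected exposure effects and
  attenuates causal estimates (visible in the scan tests). The package
  reports what the data give; it does not correct for discovery bias.
* **Nominal significance.** The scan screens at unadjusted IVW p < α
  across exposures, matching common practice in taxon-wide MR scans;
  Benjamini–Hochberg q-values are emitted alongside, clearly labelled, for
  readers who want the corrected view.
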