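---
title: "Closed-loop simulation testing of catch-at-age assessments with scaloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop simulation testing of catch-at-age assessments with scaloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scaloop runs the closed loop that underpins modern evaluation of
age-structured stock-assessment methods: an *operating model* (OM) generates
the true dynamics of a virtual fish stock, *sampling functions* draw noisy
observations from that truth, an *estimation model* (EM) is fitted to the
samples by maximum likelihood, and *results functions* collect truth and
estimates side by side across many stochastic iterations of many scenarios.
Because the truth is known exactly, the bias and precision of the assessment
can be measured directly — something impossible with real data.

This vignette documents the science inside each step: the population model
and its conventions, the observation models, the estimator and its numerics,
the experiment manager, and what the packaged tests do and do not
demonstrate.

## The operating model

The OM is an annual, single-area, single-sex age-structured model with ages
$0,\dots,A$ where $A$ is a plus group. For a stock with natural mortality
$M$, von Bertalanffy growth
$L_a = L_\infty\,(1 - e^{-k (a - t_0)})$, length–weight
$w = \alpha L^\beta$, and logistic maturity $m_a$, the unfished equilibrium
is the survivorship scan

$$N^0_a = R_0 e^{-Ma}, \qquad
  N^0_A = \frac{R_0 e^{-MA}}{1 - e^{-M}}, \qquad
  \mathrm{SSB}_0 = \sum_a N^0_a w_a m_a .$$

Recruitment follows a Beverton–Holt curve in the steepness
parameterization,

$$\mathrm{BH}(S) = \frac{4 h R_0 S}{\mathrm{SSB}_0 (1-h) + S (5h - 1)},$$

so that $\mathrm{BH}(\mathrm{SSB}_0) = R_0$ and
$\mathrm{BH}(0.2\,\mathrm{SSB}_0) = hR_0$. Annual recruitment multiplies
the curve by a lognormal deviation with the mean-bias correction,

$$R_y = \mathrm{BH}(\mathrm{SSB}_y)\, e^{\mathrm{dev}_y - \sigma_R^2/2},
  \qquad \mathrm{dev}_y \sim \mathcal N(0, \sigma_R^2),$$

so the truth is *mean-unbiased* around the curve
($\mathbb E[R_y \mid \mathrm{SSB}_y] = \mathrm{BH}(\mathrm{SSB}_y)$). A
consequence worth knowing: a run with all deviations set to zero is the
*median* trajectory, which sits a factor $e^{-\sigma_R^2/2}$ below mean
recruitment; exact equilibrium under zero deviations holds only in the
$\sigma_R \to 0$ limit, and the tests check it there.

Conventions, chosen once and shared exactly by OM and EM so they introduce
no structural mismatch:

* spawning and recruitment at the start of the year; age-0 fish are
  immature, so the within-year SSB → recruitment recursion is explicit;
* total mortality $Z_{a,y} = M_y + \sum_f s_{a,f} F_{f,y}$ with logistic
  selectivity $s_{a,f}$; survivors age by one year with plus-group
  accumulation;
* catch-at-age by the Baranov equation,
  $C_{a} = \frac{s_a F}{Z_a} N_a (1 - e^{-Z_a})$, accumulated over the
  whole year; catches are generated without implementation error — the F
  series drives the truth directly and observation error lives only in the
  sampling functions;
* survey availability at a fixed within-year timing (default mid-year):
  index $= q \sum_a s_a N_{a,y} e^{-0.5 Z_{a,y}} w_a$ (a biomass index);
* the plus group uses the length and weight of age $A$ itself, not the
  true mean age of the group;
* the age–length transition assigns age $a$ the Normal mass with mean
  $L_a$ and SD $\mathrm{cv} \cdot L_a$ between bin edges, with open-ended
  first and last bins, renormalized per age.

Time-varying dynamics are injected additively (`apply_tv()`): a targeted
scalar such as `M`, growth, or a fleet's selectivity becomes a per-year
vector `base + deviation`, which is how scenarios with, say, a pulse of
natural mortality are built.

## The observation models

* **Abundance index**: $\mathrm{obs} = \mathrm{true} \cdot e^{\varepsilon}$,
  $\varepsilon \sim \mathcal N(0, \mathrm{sds\_obs}^2)$. The noise is
  deliberately *median*-unbiased (no $-\sigma^2/2$ shift), matching the
  lognormal likelihood the estimator uses; users comparing arithmetic mean
  index to truth should expect the $e^{\sigma^2/2}$ inflation.
* **Age and length compositions**: counts
  $\sim \mathrm{Multinomial}(N_\mathrm{samp}, p)$ against the OM's expected
  composition (selected numbers at survey timing for surveys; whole-year
  catch-at-age for fisheries; lengths through the age–length matrix),
  reported as exact proportions together with $N_\mathrm{samp}$.
* **Catch**: passed to the estimator as observed without error, the
  conditioned-on-catch convention.

Process error (recruitment deviations) and observation error use separate
seed streams derived by a documented stable hash, so iteration $i$ shares
its recruitment history across all scenarios (paired comparisons) while
every scenario draws independent observation noise.

## The estimation model

The EM is a statistical catch-at-age estimator written as a TMB template,
structurally identical to the OM (the package asserts this identity to
machine precision at the true parameters). Its objective is

$$\ell = \sum_i \frac{(\log \mathrm{obs}_i - \log \mathrm{pred}_i)^2}
              {2\,\mathrm{se}_i^2}
  \;-\; \sum_j N_j \sum_b p^{\mathrm{obs}}_{jb}
        \log \max(p^{\mathrm{pred}}_{jb}, 10^{-10})
  \;+\; \sum_y \frac{\mathrm{dev}_y^2}{2\sigma_R^2} + \log \sigma_R ,$$

with predicted recruitment
$R_y = \mathrm{BH}(\mathrm{SSB}_y) e^{\mathrm{dev}_y - b_y \sigma_R^2/2}$.
The $\log\sigma_R$ term matters only when $\sigma_R$ is estimated. Fishing
mortality carries no free parameters: each year's $F$ is solved inside the
template by Newton iteration so predicted catch biomass equals the observed
catch (the Baranov catch is concave and increasing in $F$, so the Newton
steps converge monotonically; 14 iterations reach machine precision and
automatic differentiation flows through them).

Estimable parameters (each toggleable to a fixed value): $\log R_0$,
$\log M$, steepness through $h = 0.2 + 0.8\,\mathrm{logit}^{-1}(\cdot)$,
logistic selectivity per fleet, $\log q$ per survey, $\log \sigma_R$, and
one recruitment deviation per year. Defaults fix $M$, $h$ and $\sigma_R$ at
their template values and estimate the rest — the configuration that
isolates the packaged example's E0/E1 contrast on $M$.

Numerical choices:

* **Starting values** are deterministic: $R_0$ at twice a naive estimate
  (mean catch divided by yield-per-recruit at $F = M$ with maturity-shaped
  selectivity), $M$ at 0.2, selectivity at the maturity curve, $q$ matched
  to the mean index at the starting abundance, deviations at zero.
* **Optimization**: `nlminb` full Newton using the exact AD Hessian from
  TMB (typically < 10 iterations), with a gradient-only quasi-Newton
  fallback and a polishing pass whenever the gradient has not reached the
  threshold. Box bounds are wide and documented in the code; parameters
  within $10^{-6}$ of a bound are counted and reported.
* **Uncertainty**: standard errors from the inverse AD Hessian
  (`TMB::sdreport`), with derived series (SSB, recruitment, depletion,
  terminal F) via the delta method. The AD Hessian is exact, so no
  finite-difference step-size tuning enters the results.
* **Convergence**: maximum absolute gradient below $10^{-3}$ *and* a
  positive-definite Hessian. Optimizer failure is reported as a
  `fit_result` with `converged = FALSE`, never as an exception, so one
  diverged iteration cannot abort a batch.

Derived quantities use an equilibrium yield analysis: for $F$ on a grid,
equilibrium recruitment comes from the Beverton–Holt curve and
spawning-per-recruit, equilibrium yield is
$Y(F) = \mathrm{YPR}(F) \cdot R_{eq}(F)$, and $F_{\mathrm{MSY}}$ is the
grid maximum refined by golden-section search to $10^{-4}$; at $h = 1$
equilibrium recruitment is $R_0$ wherever $\mathrm{SPR} > 0$, and at the
steepness floor the yield curve collapses and
$\mathrm{SSB}_{\mathrm{MSY}}$ is reported missing with a flag.

### Recruitment bias adjustment

Penalized-likelihood recruitment deviations shrink towards zero where data
are weak. With the full lognormal correction ($b_y \equiv 1$) that makes
*mean* recruitment biased low in data-poor years; with no correction it is
biased high in data-rich years. `run_bias_adjust()` calibrates the per-year
factor iteratively: fit with $b_y = 1$, set
$b_y = \max(0,\, 1 - \mathrm{SE}(\mathrm{dev}_y)^2/\sigma_R^2)$, smooth
with a centered 5-point moving average, refit, and stop when
$\max_y |\Delta b_y| < 0.01$ or after 5 passes. Data-free years approach
$b_y = 0$ (their deviation SE approaches $\sigma_R$); perfectly informed
years approach $b_y = 1$. The packaged validation of this machinery uses
the regime where the correction actually matters — a sardine-like stock
with high recruitment variability ($\sigma_R = 0.6$, typical of small
pelagics) observed only over the recent third of its history, with the
structural parameters held at their true values so the recruitment-bias
mechanism is isolated from scale-parameter sampling skew — and measures the
relative error of mean recruitment under paired seeds.

### Retrospective analysis

`run_retrospective()` refits after truncating the model (and every
observation, including the conditioning catches) at $T - p$ for peels
$p = 0,\dots,n$. The summary statistic is Mohn's rho,
$\rho = \mathrm{mean}_p\,[X_p(T-p) - X_0(T-p)]/X_0(T-p)$, stated here
explicitly because naming conventions vary. Under a matched OM/EM, rho
should be centered near zero; the test suite checks this by Monte Carlo on
the sardine-like stock.

## The scenario engine

Experiments are described by semicolon-delimited plain-text case files
(`key; value`, values parsed by a closed grammar of numbers, quoted text,
`c(...)`, `seq(a, b, by = s)` and `list(...)` — deliberately not a
general-purpose evaluator) combined into scenario IDs such as
`D1-E0-F0-M0-R0-cod`: the data case `D` expands to `index*`, `lcomp*` and
`agecomp*` files, and `E`, `F`, `M`, `R` map to estimation toggles, the
fishing pattern, time-varying natural mortality, and retrospective peels.
Each scenario × iteration writes a folder of plain-text outputs (OM truth
tables, sampled data, EM results, a config echo and a stage log);
`get_results_all()` harvests everything into long-format
`ss3sim_scalars.csv` and `ss3sim_ts.csv` with paired `_om`/`_em` columns
and ready-made `_re` relative-error columns. Re-running an identical
configuration, serial or parallel, reproduces the csv files byte for byte
(per-fit wall time is recorded in each iteration folder but deliberately
kept out of the harvested csv for that reason).

## The packaged stocks and study conditions

Three generic life histories ship as editable text files: cod-like
(slow-growing, long-lived: $A = 25$, $L_\infty = 120$ cm, $k = 0.1$,
$M = 0.2$), flatfish-like (fast-growing, long-lived: $A = 20$, $k = 0.3$)
and sardine-like (fast-growing, short-lived: $A = 8$, $k = 0.4$,
$M = 0.4$), all with $h = 0.65$ and $\sigma_R = 0.4$. Only the cod value
of $M$ should be read as meaningful beyond "generic demersal gadoid"; the
remaining parameters are documented defaults in `inst/extdata/models/`
(schema in `SCHEMA.md`), intended to be copied and modified.

The packaged cod experiment fishes a ramp from zero to approximately
$F_{\mathrm{MSY}}$ ($0.13\,\mathrm{yr}^{-1}$) over 1974–1993 and holds it
constant thereafter — a fished-near-MSY history with terminal depletion
around 0.35. The survey index is biennial over 1974–2012 with log-SD 0.1
(data case D0) or 0.4 (D1). Compositions are biennial over 1994–2012 at
effective sample size 50 for both fleets: a stock with a modern data-rich
period and a data-poor history. That choice matters: saturating the model
with annual high-$N_\mathrm{samp}$ compositions makes $M$ estimable to
within half a percent, at which point fixing versus estimating $M$ (the
E0/E1 contrast) is indistinguishable — the contrast the example is designed
to show lives in the moderate-information regime.

## What the tests show — and what they do not

The synthetic-data generator emulates lognormal index error, multinomial
composition error and lognormal recruitment variability around a
Beverton–Holt curve, all correctly specified relative to the estimator.
Passing self-tests therefore demonstrate that the estimator is consistent
and approximately unbiased *when its structure matches the truth* and that
the closed loop is plumbed correctly. They do not demonstrate robustness to
the things real data do: overdispersed and correlated compositions, ageing
error, time-varying selectivity or catchability, implementation error in
catches, or model misspecification generally. Those questions are exactly
what the scenario machinery (time-varying injection, estimation toggles)
is for, and they remain the user's experiment to design.

Monte-Carlo problem sizes in the shipped tests were chosen to keep the
default suite comfortably runnable on a laptop: 30 iterations for the cod
2×2 example grid and self-test recovery checks, 50 paired iterations for
the bias-adjustment contrast on the small sardine configuration, 12
iterations × 5 peels for the retrospective null, and $10^4$ draws for
noise-calibration checks. Directional conclusions at these sizes come with
sampling noise of a few percent; anyone reusing the package for real
method evaluation should scale iterations up (the paper-style experiment
used 100) and run the convergence screens (`max_gradient`,
`covariance_ok`, `n_params_on_bounds`) that the results tables carry.

## Known limitations

* Annual time step, one area, one sex; no seasons, tagging, or growth
  morphs.
* The EM assumes stationary biology; it can be *confronted* with
  time-varying truths (that is the point of the M case) but cannot
  estimate time-varying parameters itself.
* $\sigma_R$ estimation is available as a toggle but the default keeps it
  fixed, as in the packaged experiments.
* The bias-adjustment scheme is an iterative SE-based calibration with the
  mean-unbiasedness contract as its test; it is a documented
  simplification, not a claim of equivalence to any particular assessment
  platform's internals.
* Catch is conditioned, not estimated: datasets whose catches are
  inconsistent with any $F \le 20\,\mathrm{yr}^{-1}$ under the assumed
  biology will produce a diagnosed non-converged fit rather than a
  reweighted compromise.
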