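---
title: "Modelling copper dose-toxicity across soils: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling copper dose-toxicity across soils: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuphytox)
```

## The problem

Copper accumulates in agricultural topsoils and inhibits plant growth, but
the dose that matters is not the total metal load: only the reactive pools
— water-soluble, exchangeable, and specifically adsorbed Cu, summed by an
EDTA extraction together with the natural background — are available to
roots. The same EDTA-extractable concentration can halve biomass in one
soil and be harmless in another, because pH, organic carbon (OC), cation
exchange capacity (CEC) and Mn/Fe oxide pools modulate both availability
and the shape of the response. `cuphytox` implements the full analysis
chain for replicated pot bioassays conducted across such a soil panel:
per-soil dose-response fitting, threshold derivation, threshold-on-soil
regression, and a joint model in which the curve parameters themselves are
functions of soil properties.

## The dose-response model and its sign convention

Relative growth $Y$ (% of the group's control) against
$X = \log_{10}$ EDTA-extractable Cu (mg kg$^{-1}$) follows a log-logistic
curve

$$Y = \frac{Y_0}{1 + e^{-b\,(X - a)}},$$

with $Y_0$ the undisturbed growth level, $a = \log_{10}\mathrm{EC50}$, and
$b$ the slope. We adopt the convention in which **toxicity means
$b < 0$**: the fitter works with an internal positive slope $s$ on the
decreasing form $Y = Y_0/(1 + e^{s(X-a)})$ and reports $b = -s$. Under
this convention the reference parameter sets (negative $b$ over the whole
panel's pH range) and the closed-form threshold ratio

$$\frac{\mathrm{EC50}}{\mathrm{EC10}} = 10^{-\ln 9 / b}$$

are simultaneously coherent. The constant is $\ln 9 = 2.1972$; a rounded
2.2 is sometimes quoted. The inhibition threshold is
$\log_{10}\mathrm{ECx} = a + \ln\!\big(\tfrac{q}{1-q}\big)/(-b)$ with
$q = x/100$, so EC50 $= 10^a$ exactly, and the inverse
("limit concentration") formula used by `predict_limit_concentration()` is
$X = a + \ln\!\big(\tfrac{Y_0 - Y}{Y}\big)/(-b)$, the exact algebraic
inverse of the curve.

## The joint covariate-parameterized model

Across a panel the per-soil parameters are not free: location follows

$$a = K_1 + K_2\,\mathrm{pH} + K_3 \log \mathrm{OC} + K_4 \log
\mathrm{CEC},$$

(the form is fixed; these three covariates are consistently the dominant
correlates of $a$), while the slope form is configurable,
$b = \beta_0 + \beta_1\,\mathrm{pH}\,(+\ \beta_2\,\mathrm{OXMn})$ by
default — pH plus, for tomato, oxalate-extractable Mn, both entering
untransformed (the OX-Mn coefficient is per mg kg$^{-1}$, hence its small
magnitude). `screen_b_covariates()` reproduces the screening step: Pearson
correlation of per-soil fitted $b$ (and $a$) with each candidate,
ranked by $|r|$ and flagged at $p \le 0.05$. `fit_joint()` then minimizes
the pooled SSR over $(Y_0, K_1\ldots K_4, \beta)$ for one species x
treatment. $Y_0$ is fitted, not fixed at 100: fitted values near 100
confirm the normalization rather than assume it.

Numerical strategy: the optimizer is warm-started from the per-soil fits
(OLS of per-soil $a$ on $(1,\mathrm{pH},\log\mathrm{OC},
\log\mathrm{CEC})$ and of $b$ on the chosen covariates), refined by
Nelder-Mead with a BFGS polish, with two additional jittered starts drawn
from a seeded stream (default seed 0 — results are deterministic). The
exponent is clamped at $\pm 700$ to avoid overflow; a fit whose evaluated
$b$ is non-negative on any fitted soil is reported non-converged rather
than silently accepted. $R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$ about the
pooled grand mean; the overall $p$ is an F-test against the constant
model with numerator df equal to the number of free parameters minus one.
`grid_oracle_fit()` provides a brute-force check: exhaustive SSR
evaluation over up to three coefficients with the rest pinned, used in the
test suite to verify the optimizer is never beaten by more than 1e-6.

## Per-soil fitting and thresholds

`fit_loglogistic()` uses the same Nelder-Mead + BFGS multistart (five
starts) from a moment-based initialization: $Y_0$ from the top of the
curve, $a$ by interpolating the half-maximal response, $s$ from the
steepest observed log-slope. Convergence tolerance is 1e-10 on SSR with a
10^4 iteration cap. A group is declared unfittable — mirroring panels
where no appropriate dose-response model can be derived for some soils —
when the slope magnitude falls below 0.05 (no dose effect) or the implied
EC50 leaves the window [min dose / 10, max dose x 10].

Confidence intervals are percentile bootstrap (default $B = 1000$):
replicates are case-resampled within each dose level, the curve refit
(warm-started at the original estimate), and the 2.5/97.5 percentiles
taken; failed refits are dropped and counted, and more than 50% failures
aborts as "unstable fit". With 3 replicates per dose this interval is
known to run slightly below nominal coverage, and more so for the
extrapolated EC10 than for EC50 (see Limitations).

Leaching factors are per-soil ratios ECx(leached)/ECx(unleached) over
converged pairs, summarized by the mean with the **standard error** as the
headline spread; the SD is also returned since the "mean ± spread"
notation in field reports is ambiguous. `summarize_thresholds()` reports
range, median, mean and fold-variation (max/min) over converged fits and
lists exclusions.

## Threshold regressions

`ols_fit()` is closed-form least squares with standard normal-error
inference; `forward_select()` starts from the best single predictor by
$R^2$ and greedily adds the $R^2$-maximizing candidate while every
entering coefficient keeps $p \le \alpha$ (default 0.05, at most 3 terms,
ties broken by candidate order then name). The candidate pool is pH,
logOC, logCEC, CaCO3, logOXMn, logCDMn, logCDFe (+ clay when present);
electrical conductivity is excluded by default as it is never selected in
practice. OC, CEC and the oxide pools enter as log10; pH, CaCO3 and clay
raw. Only converged ECx point estimates enter, on the log10 scale.

A caution established by our simulations: greedy forward selection is not
guaranteed to recover a generating structure on a small, collinear panel.
On the 17-soil reference covariates, thresholds generated from a
(logCDMn, logCEC, CaCO3) structure are better explained *single-handedly*
by logCDFe than by logCDMn, so the greedy path starts at logCDFe and,
having no removal step, can never return the generating trio. This is a
property of the procedure and panel, not an implementation defect; users
needing structure discovery on such panels should treat the selected model
as predictive, not causal.

## The synthetic bioassay generator

No raw biomass data are distributed with multi-soil Cu bioassay studies of
this design, so the generator is the package's substrate for testing every
downstream stage by parameter recovery. It emulates:

* the 17-soil reference panel (`load_reference_soils()`; CaCO3 below the
  0.5% detection limit stored as 0.25, half the limit);
* the pH-stratified spiking design: control plus seven doubling doses,
  12.5-800 mg/kg below pH 5, 25-1600 in [5, 7] (boundaries inclusive to
  the middle stratum), 37.5-2400 above pH 7;
* EDTA-extractability as background + recovery x dose, with a per-soil
  log-normal background (median 5 mg/kg, sdlog 0.5) and recovery
  $r = \mathrm{clip}(0.95 - 0.02\,\mathrm{CaCO3} - 0.05(\log_{10}
  \mathrm{CDFe} - 3.5),\ 0.3,\ 0.95)$ — a deliberately simple mass-balance
  stand-in encoding that carbonates and Fe oxides depress recovery;
* the logistic response with parameters from the species' linear forms;
  leaching simulated as a pure $+0.18$ (tomato) / $+0.03$ (bok choy)
  log10-unit shift of $a$, the simplest mechanism that produces ratio-type
  leaching factors (about 1.5 for tomato EC10, since $10^{0.18} = 1.51$);
* multiplicative Gaussian noise truncated at zero, default cv 0.10 and 3
  pots per dose (no replicate count or variance is published for such
  assays; these are declared choices, and cv 0.10 places the joint-fit
  $R^2$ in the >0.90 regime reported for real panels);
* optional hormesis: a smooth Gaussian-shaped multiplier on the mean
  response, peaking one doubling step below EC50 (width 0.25 log10
  units), with configurable maximum (e.g. 1.29 reproduces the ~129%
  low-dose overshoot phenomenology) — off by default, and deliberately
  not a mechanistic Brain-Cousens term.

Generated tables carry their generating truth as an attribute, and
`relative_growth` holds the simulated response directly; re-deriving it
from the noisy controls via `normalize_relative_growth()` is the
realistic path (each soil x treatment x species group is normalized by
its own control mean — undisturbed growth differs between soils, so a
global control would confound fertility with toxicity).

What the generator does **not** emulate: geochemical speciation and
sorption, pot-level spatial or temporal effects, measurement error in the
soil covariates themselves, non-logistic response shapes, and
between-replicate correlation. Passing recovery tests therefore shows the
estimators are correct under the stated statistical model, not that the
model is adequate for any particular field dataset.

## Problem sizes and reproducibility

The test-suite simulations use the full 17-soil design (408 observations
per species x treatment at 3 replicates) for recovery and variance checks,
6-soil subsets for the grid-oracle comparisons, and 200-repetition
simulations (B = 1000) for bootstrap coverage — sizes chosen so each
property is measured with useful precision while the whole suite stays
quick on a laptop. All randomness (generator, multistart jitter,
bootstrap) flows from explicit integer seeds, and `run_pipeline()` stamps
its artifacts with the configuration hash and seed; a rerun with the same
configuration is byte-identical.

## Known limitations

* Percentile bootstrap intervals with 3 replicates per dose undercover:
  empirically ~87-90% for EC50 and ~86-91% for EC10 at nominal 95%, as
  expected from the (n-1)/n bias of within-dose resampling at n = 3. BCa
  or profile-likelihood intervals would improve this but are out of
  scope.
* $Y_0$ is fitted per curve; hormesis-aware fitting is not implemented,
  so strongly hormetic data will inflate $Y_0$ rather than resolve the
  low-dose peak.
* The joint model's covariate forms are linear by construction; clay is
  carried as an optional covariate but the reference panel has no clay
  values, so models referencing clay fail fast with a clear message.
* Forward selection is greedy (see above); no all-subsets or
  information-criterion search is provided.
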