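---
title: "Methods: tissue pharmacokinetics of intraperitoneal cisplatin from microdialysis sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue pharmacokinetics of intraperitoneal cisplatin from microdialysis sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipecpk)
```

## The experiment this package models

During hyperthermic intraperitoneal chemotherapy (HIPEC) a heated
cisplatin solution is circulated in the abdominal cavity after
cytoreductive surgery. How much free drug actually reaches the tissues it
is meant to treat — and for how long — is the pharmacological question.
The experimental design emulated here answers it in a large porcine
model: microdialysis catheters are placed in the peritoneal lining of
several abdominal organs (two liver positions, superficial and profound
positions in the stomach and rectum wall, three peritoneal quadrants —
nine "compartments" per animal), drug is given as a fractionated bolus
schedule (50 % of the total dose at time 0, 25 % at 30 min, 25 % at
60 min; 90 min of perfusion; total dose 100 mg/m² with body surface area
`SA = 0.0970 · W^0.633` for a pig of weight `W` kg), and each catheter
collects twelve interval-averaged dialysate samples over eight hours:
every 30 min to 240 min, then every 60 min to 480 min.

Microdialysis measures only a fraction of the true extracellular
concentration. Each catheter is therefore calibrated by
retrodialysis-by-drug: with drug at concentration `C_perf` in the
perfusate, the relative recovery is `RR = 100 (1 − C_dial / C_perf)` and
tissue concentrations are reconstructed as
`C_tissue = 100 · C_dial / RR`. These two maps are exact inverses of one
another, which the test suite exploits as a round-trip identity.
Recoveries outside (0, 100] are physically impossible and mark a
malfunctioning probe; such catheters are excluded, mirroring the
displacement losses of the real experiment. Where a catheter has two
calibration samples their recoveries are averaged — the calibration
protocol produces two samples but no published rule for combining them,
and the mean is the natural symmetric choice.

## The kinetic model

Only the tissue is observed, so the two-compartment description (a
central perfusate compartment feeding a peripheral tissue compartment at
a constant rate, with first-order loss from the tissue) collapses to an
identifiable three-parameter form for the tissue concentration:

$$
\frac{dC}{dt} = k_{in}\,\mathbf 1(t \le t_{in}) - k_e\,C, \qquad C(0)=0,
$$

with closed form

$$
C(t) = \frac{k_{in}}{k_e}\left(1 - e^{-k_e t}\right) \ (t \le t_{in}),
\qquad
C(t) = C(t_{in})\,e^{-k_e (t - t_{in})} \ (t > t_{in}).
$$

* `k_in` (µg·mL⁻¹·min⁻¹) — zero-order rise rate of the tissue
  concentration while the perfusate still supplies drug;
* `t_in` (min) — duration of that input window;
* `k_e` (min⁻¹) — first-order elimination rate, `T1/2 = ln 2 / k_e`.

The central compartment's initial content, bolus amounts and transfer
rate are not separately identifiable from tissue data; the exported
`map_central_parameterization()` documents the equivalence and computes,
by exact event-driven bookkeeping, the input windows implied by a given
central content, bolus schedule and depletion rate. By default the three
boluses are assumed to keep the central pool non-empty until a single
depletion time, giving one contiguous input window — this matches the
observed unimodal curves, whose peak times (101–124 min) exceed the
90-min perfusion. For the same reason the drain at 90 min is *not*
imposed as a hard cutoff on `t_in`: the fitted input window may extend
beyond the perfusion because drug already in the interstitial route keeps
arriving at the catheter membrane after the cavity is emptied. A
gap-aware variant (windows with idle periods between boluses) is
available through the mapping function but is not part of the fitted
model.

Derived parameters are model-based: the curve has a unique peak at
`t_max = t_in` with `C_max = C(t_in)`, and `AUC_0–last` is the analytic
integral of the fitted curve to the last sampling time (480 min), not an
observed-data trapezoid. A microdialysis sample physically integrates
concentration over its collection window, so the model predicts each
sample by the interval average computed from the analytic antiderivative
(`pk_interval_average()`); point prediction at the interval midpoint is
available as an option. Closed form, interval averages and AUC are each
verified in the test suite against independent numerical oracles
(adaptive ODE integration, adaptive quadrature, dense trapezoids) to
relative errors below 1e-6.

## Estimation

Each tissue compartment is fitted separately by a nonlinear mixed-effects
model on the log scale: for animal $i$ and sample $j$,

$$
\log C^{obs}_{ij} = \log \bar C\big(k_{in} e^{b_{1i}},\, t_{in},\,
k_e e^{b_{2i}};\, [t_{j,0}, t_{j,1}]\big) + \varepsilon_{ij},
$$

with independent animal-level random effects
$b_{1i} \sim N(0, s_1^2)$, $b_{2i} \sim N(0, s_2^2)$ and residual
$\varepsilon_{ij} \sim N(0, \sigma^2)$. Choices behind this structure:

* **Log-normal (proportional) error** — the concentrations span more
  than an order of magnitude across compartments, and the assay precision
  is itself relative (~20 %).
* **Random effects on `log k_in` and `log k_e` only; `t_in` common to
  the tissue** — with at most eight animals a third variance component is
  not supportable, and peak times vary little across compartments.
* **Censoring** — dialysate values below the LLOQ (0.030 µg/mL) are
  flagged and excluded from the fit by default; imputation at LLOQ/2 is
  available (`lloq_handling = "impute_half"`). Exclusion is the
  conservative default since the true likelihood contribution of a
  censored interval average is not identified without further assumptions.
* **Duplicate catheters** in the same tissue and animal enter as separate
  observation series sharing the animal's random effects.

The marginal likelihood integrates over $(b_{1i}, b_{2i})$ by a Laplace
approximation. Because the model is *linear* in $b_{1i}$ on the log
scale, the conditional mode of $b_{1i}$ is available in closed form and
the inner optimisation is one-dimensional in $b_{2i}$; the $2\times2$
curvature at the mode uses the exact $b_1$ block and central differences
for the $b_2$ terms. The outer problem — three fixed effects and three
log-scale variance parameters — is solved by bounded quasi-Newton
(`nlminb`), restarted from its own optimum until the objective cannot be
improved (the Laplace surface is only piecewise smooth through the inner
modes, which can trigger spurious "false convergence" reports one step
from the optimum). Starting values come from a two-stage scheme: a pooled
nonlinear least-squares fit of the fixed effects, then per-animal
least-squares deviations whose dispersion seeds the variance components.
This lands the optimiser in the right basin and makes the noise-free
limit essentially exact (the test suite checks recovery to 0.1 % there).
In the correctness tests the Laplace value is compared against an
independent quadrature oracle — exact Gaussian integration over the
linear effect and adaptive quadrature over the other — and the full fit
against `nlme::nlme` on the same data.

Numerical floors: the residual SD is bounded below at 1e-3 and the
random-effect SDs at 1e-4 (log scale), keeping the likelihood bounded
when simulated data are noise-free; variance components pinned at a bound
are excluded from the curvature matrix used for Wald uncertainty.
Exponentiated fixed effects are the population median parameters;
per-animal empirical-Bayes modes give per-catheter estimates, which are
mapped through the closed form into `AUC_0–last`, `C_max`, `T_max` and
`T1/2` per catheter. Population confidence intervals are Wald on the log
scale via the delta method — the convention adopted because the original
analysis does not state how its intervals were computed.

## Between-tissue comparisons and limits of agreement

Comparisons of derived parameters between compartments operate on the
log-transformed per-catheter values through a linear mixed model with a
tissue fixed effect and a random animal intercept; the back-transformed
coefficient is a ratio of estimated medians with Wald 95 % intervals.
The ratios are computed from this second-stage model on per-catheter
parameters (rather than directly from the NLME fixed effects) because the
comparisons and their animal-level pairing concern the per-catheter
quantities. No multiplicity adjustment is applied — raw p-values with a
5 % threshold are reported, with an adjustment available to the caller
via `stats::p.adjust` if desired. When catheter dropout leaves the
animal intercepts free to interpolate the data (almost no animal carrying
both tissues), the residual variance collapses and the ratio's
uncertainty is reported as `NA` rather than as a spuriously exact
interval.

Reproducibility between duplicate catheters is summarised by limits of
agreement on the log scale: `log(parameter) ~ 1 + (1 | animal)` within an
organ, with residual SD $\sigma$ describing catheter-level scatter. The
difference of two catheters in the same animal has SD $\sqrt 2 \sigma$,
so 95 % of same-animal catheter ratios fall within a factor
$\exp(1.96 \sqrt 2 \sigma)$ of each other. The factor's confidence
interval is a parametric bootstrap (simulate from the fitted model,
refit; 1000 replicates by default, fixed seed).

## The synthetic-data generator

No animal-level data are published, so the package ships a generator
(`generate_experiment()`) that emulates the study design and makes every
stage testable end to end. Defaults, fixed once as the study conditions:

* 8 animals × 9 compartments, one catheter each (72 planned series; the
  published accounting lists 62 catheters against a 9×8 layout — the
  generator plans the full layout and treats the difference as part of
  the failure process);
* population kinetic parameters per compartment obtained by inverting the
  closed form at the published per-compartment medians of `C_max`
  (0.45–3.11 µg/mL), `T_max` (101–124 min) and `T1/2` (16–41 min);
* between-animal log-SDs of 0.4 on `k_in` and 0.15 on `k_e` — synthetic
  values (no variance components are published) chosen so that simulated
  confidence intervals have the printed order of magnitude; `t_in` is
  generated fixed per compartment, matching the estimation model;
* per-catheter recoveries drawn from the published per-compartment means
  and SDs (70–91 %, SD 4–22), truncated to (0, 100];
* residual log-SD 0.2, matching the assay's ~20 % intermediary
  precision;
* censoring below the LLOQ of 0.030 µg/mL, and whole-series catheter
  loss with probability 19/62 (independent Bernoulli), mirroring the
  exclusion of displaced catheters.

The same drawn recovery corrupts the data and calibrates the correction,
so corrupt-then-correct is an identity by construction; the option
`miscalibrated_rr_sd` injects calibration error to stress-test the
pipeline. Everything is deterministic given `(config, seed)`.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial diffusion between tissue depths
(depths are independent compartments with their own parameters),
temperature heterogeneity of the perfusate, systemic re-circulation of
drug, non-log-normal assay error, and any informativeness of catheter
failure (losses are missing completely at random).

## Problem sizes and runtime choices

The shipped analysis and tests use the design sizes of the experiment
itself: 8 animals, 9 compartments, 12 samples per catheter. Oracle
comparisons run on 1000 random parameter draws; the dropout Monte-Carlo
uses 500 simulated experiments; the limits-of-agreement recovery uses 500
replicates of an 8-animal, 16-catheter design; bootstrap intervals in the
analysis scripts use 500 replicates (the function default is 1000). These
sizes give stable averages while keeping a full run of the suite in the
low minutes on a single core.

## Known limitations

* The Laplace approximation is not exact for the `k_e` random effect;
  against the quadrature oracle the marginal log-likelihood agrees to
  ~1 % at realistic noise, which is ample for point estimation here but
  would matter for likelihood-ratio machinery built on top.
* With eight animals the population-median estimate of `k_in` carries
  ~14 % sampling error from the between-animal draw alone; parameter
  recovery must be judged against the realized animals' truth, and the
  package's tests do exactly that.
* Tissue compartments are fitted independently; no information is shared
  across tissues, matching the original analysis but foregoing shrinkage
  a joint model could provide.
* Censored observations are excluded rather than integrated over; with
  the default truth this affects mainly the late tail, biasing `k_e`
  slightly when half-lives are short.
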