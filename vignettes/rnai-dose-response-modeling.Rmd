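---
title: "Comparing kinetic models of RNAi dose-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing kinetic models of RNAi dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaikin)
```

## The modeling problem

siRNA transfection experiments measure a *knockdown ratio*: the
steady-state level of a target mRNA (or its protein) in treated cells
divided by the level in cells receiving a non-targeting control, across a
ladder of siRNA doses. The shape of that curve discriminates between
hypotheses about RISC kinetics — in particular whether silencing keeps
deepening with dose (mass-action behavior) or saturates once the siRNA
supply overwhelms the silencing machinery (Hill behavior).

`rnaikin` treats the measurement as the equilibrium of

$$\frac{dX_m}{dt} = k_m - d_m X_m - \delta(X_m, X_s), \qquad
  \frac{dX_p}{dt} = k_T X_m - d_p X_p,$$

with the siRNA amount $X_s$ constant over the experimental window (the
siRNA-RISC complex is long-lived relative to the 48–60 h measurement
horizon) and four candidate degradation laws $\delta$: mass action
($k_1 X_s X_m$), cooperative mass action ($k_2 X_s^{h_2} X_m$), an
enzymatic law ($c_3 k_3 h_3 X_s X_m/(c_3 + k_3 h_3 X_m)$ — Michaelis–Menten
in the mRNA at fixed dose, reflecting catalytic RISC turnover), and a
phenomenological Hill law
($d_4 X_s^{h_4}/(\theta_4^{h_4}+X_s^{h_4})\cdot X_m$), the only one that
saturates in $X_s$.

## Steady states and what actually gets fitted

Each law has a closed-form positive equilibrium; dividing by the control
equilibrium $k_m/d_m$ gives the knockdown ratio the models are fitted on.
Two structural facts drive the parametrization:

* **The transcription rate cancels.** For models 1, 2 and 4 the ratio
  depends only on $d_m$ and the model's own parameters. Model 3's ratio
  retains the transcription rate only through the quotient $c_3/k_m$, so
  the package never represents $k_3$, $h_3$, $c_3$ separately: the fitted
  quantities are the clustered pair $(k_3h_3,\; c_3/k_m)$, which is exactly
  what ratio data can identify. Concretely,
  $$r_3(X_s) = \frac{-b + \sqrt{b^2 + 4\,(c_3/k_m)\,k_3h_3\,d_m}}{2\,k_3h_3},
    \qquad b = (c_3/k_m)(d_m + k_3h_3 X_s) - k_3h_3,$$
  the positive root of the equilibrium quadratic divided through by $k_m$;
  at $X_s = 0$ it is identically 1.
* **Protein ratios equal mRNA ratios.** At equilibrium
  $X_p = (k_T/d_p)\tilde X_m$, so the translation gain cancels between
  treatment and control. Protein datasets therefore use the same ratio
  formulas with their own parameter values; $k_T$ and $d_p$ are never
  fitted.

$d_m$ is fixed at $\ln 2/40 \approx 0.0173\,\mathrm{min^{-1}}$ (a
40-minute mRNA half-life, appropriate for short-lived reporter
transcripts) and never estimated: ratio data constrain only the *relative*
strength of RNAi versus basal turnover, and fixing $d_m$ anchors that
scale.

Limiting relationships connect the family: model 2 with $h_2 = 1$ *is*
model 1; model 3 with fast cleavage ($c_3 \gg k_3h_3 X_m$) degenerates to
model 1 with $k_1 = k_3h_3$; model 4 at doses far below $\theta_4$
linearizes to model 2 with $k_2 = d_4/\theta_4^{h_4}$, $h_2 = h_4$. The
test suite asserts each of these on dose grids, because the fitting
conclusions (mass action ≈ enzymatic; Hill wins when the data saturate)
are consequences of exactly these limits.

## Units

Doses are pmol per transfection well (2 mL), matching how transfection
experiments are reported; `pmol_to_molar()` converts when molar units are
needed (200 pmol in 2 mL = 100 nM, 0.1 pmol = 50 pM). mRNA and protein
levels are arbitrary units; $k_m$ defaults to 1 a.u./min wherever it
cancels. Fitting against pmol doses is the default; fitting against molar
concentrations just rescales the dose axis, which the rate constants
absorb, so the choice does not affect model ranking.

## Fitting

The objective is the SE-weighted squared error
$\sum_i \big((y^{\mathrm{model}}_i - y^{\mathrm{data}}_i)/SE_i\big)^2$
over all dose points, dose 0 included (its model prediction is exactly 1,
so it contributes only when noise shifts the control). When a dataset has
no usable standard errors — the realistic situation for weakly expressed
targets where triplicate SEs are unreliable — the unweighted sum of
squares is used instead; the package refuses to divide by an SE at or
below $10^{-6}$ rather than silently clipping.

The search contract is *seeded global stochastic minimization*: the
surface is multimodal in log-parameter space (notably for the Hill law,
whose exponent trades off against $\theta_4$). The implementation runs
`restarts` independent differential-evolution passes (rand/1/bin, population
$\max(4d, 12d)$ for $d$ free parameters, 80 generations, $F = 0.8$,
$CR = 0.9$) on a log10-scaled box, each polished with L-BFGS-B, keeping the
best minimum. Every restart re-seeds the RNG from `seed + restart`, and
the caller's RNG state is untouched, so identical options give identical
fits. Search bounds: rate constants in $[10^{-8}, 10^2]$, Hill exponents
in $[0.05, 10]$, $\theta_4 \in [10^{-4}, 10^3]$ pmol, and
$c_3/k_m \in [10^{-8}, 10^6]$ — the wider box for $c_3/k_m$ is needed
because its realistic fitted values sit around $10^3$ and the
fast-cleavage regime that makes model 3 identifiable-at-all lies above
that. An optional constrained mode restricts Hill exponents to $\ge 1$
(the biologically interpretable "at least one binding site" regime); on
saturating data whose unconstrained cooperative fit prefers $h_2 < 1$,
the constrained optimum lands on the boundary $h_2 = 1$ and reproduces
the mass-action fit, as the nesting demands.

Raw errors are not comparable across models of different complexity in
absolute terms, so two comparisons are reported:

* **Normalized fit error** — each model's raw error divided by the largest
  raw error among the four (the worst model scores exactly 1). If all raw
  errors are zero (noise-free ties) all are reported as 1.
* **Leave-one-out prediction error (PE)** — for each dose point, refit on
  the remaining points and score the held-out prediction with the same
  per-point error term; average over folds, then normalize against the
  worst model. Every point, including dose 0, is held out like any other.
  Fold $i$ uses seed `seed + 1000·i`, so folds are independent but
  reproducible; a fold whose fit fails is flagged and excluded with a
  warning rather than poisoning the average.

## The synthetic-data generator

No public measurement tables exist for this experimental design, so the
generator is the package's stand-in for the wet-lab data, emulating its
statistical structure: the 14-dose grid $\{0, 0.001, 0.01, 0.05, 0.1,
0.5, 1, 10, 20, 40, 60, 80, 100, 200\}$ pmol, biological triplicates, and
ratio-valued observations. Each replicate is
$\text{true ratio} \times L$ with $L$ lognormal with mean 1 and
coefficient of variation `cv`
($\sigma_{\log} = \sqrt{\log(1+cv^2)}$, $\mu_{\log} = -\sigma_{\log}^2/2$):
ratios are positive and fold-change-like, so multiplicative noise is the
natural error model, and the mean-1 parametrization keeps replicate means
unbiased. The reported SE is the sample SD over $\sqrt{n}$, exactly as an
experimentalist would compute it. The default `cv = 0.1` was chosen once
as a visually realistic triplicate spread for qPCR ratio data; no numeric
noise magnitude is available to calibrate against, so `cv` is a simulation
knob, not an estimate.

Two caveats on what the generator does *not* emulate: qPCR's ΔΔCt error
propagation (noise there is multiplicative per-replicate but correlated
through the shared reference gene) and FACS population structure
(knockdown ratios of means over skewed fluorescence distributions).
Passing recovery tests on synthetic data therefore demonstrates that the
estimator is consistent and the comparison machinery ranks correctly under
the assumed noise; it does not certify performance under real measurement
error. A small statistical point the tests respect: at $n = 3$ the sample
SD underestimates $\sigma$ in expectation by the factor
$c_4(3) = \sqrt{2/2}\,\Gamma(3/2)/\Gamma(1) \approx 0.886$, so the
Monte-Carlo check of the SE formula asserts against the $c_4$-corrected
expectation.

## The ODE oracle

`simulate_timecourse()` integrates the full system with `deSolve::lsoda`
(stiff-capable, rtol $10^{-8}$ — rate constants span $\sim 10^{-4}$ to
$10^3$), holding $X_s$ constant, default initial condition the
negative-control equilibrium (cells expressed the target constitutively
before transfection). Its role is adversarial: the closed-form steady
states are verified against 48-hour (2880 min) integrations — about 72
mRNA half-lives, so the transient is long gone — across random parameter
sweeps. The protein default $d_p = \ln 2/1500\,\mathrm{min^{-1}}$ (25 h
half-life, typical of stable reporters) means *protein* trajectories are
still visibly relaxing at 48 h; only the mRNA steady state is used as the
oracle target, and protein ratios at equilibrium are anyway identical to
mRNA ratios.

## Numerical choices and degenerate inputs

* Model 3's ratio uses the $-b + \sqrt{b^2 + c}$ root directly; for the
  parameter ranges searched the discriminant term keeps $\ge 6$
  significant digits, and the tests tolerate a float excess of $10^{-9}$
  above 1 at dose $\approx 0$. Zero dose returns exactly 1 for every model
  by construction of the formulas, not by special-casing.
* `weighted_sse` with any SE $\le 10^{-6}$ raises an error naming the
  unweighted alternative; `fit_model(weighted = NULL)` auto-selects
  weighting from the dataset so noise-free synthetic data (all SEs zero)
  fit unweighted without ceremony.
* Reports print at 3 significant figures, the precision at which fitted
  rate constants of this kind are meaningfully distinct.

## Problem sizes used in the checks

The test suite fits on the 14-dose grid with 2–10 optimizer restarts;
the steady-state oracle sweeps 100 random (model, parameter, dose)
triples in the acceptance script and 24 in the unit tests; the LOO
comparison runs all four models on one noisy Hill-generated triplicate
dataset (56 fold fits). These sizes make the whole suite complete in
about a minute while leaving every conclusion at its stated tolerance.

## Known limitations

* Deterministic, population-average models only: no stochastic single-cell
  extension, no transfection-efficiency heterogeneity.
* siRNA decay over the horizon is neglected (constant $X_s$); a slow decay
  would shift high-dose points mildly toward weaker knockdown.
* Identifiability: on saturating data, model 3's two parameters are only
  jointly constrained ($c_3/k_m$ runs to its upper bound as the law
  degenerates to mass action); the package reports the fit it found, and
  the model-comparison layer — not the parameter values — carries the
  scientific conclusion there.
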