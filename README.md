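# rnaikin

Kinetic modeling of siRNA-mediated mRNA degradation in mammalian cells.

Transfecting a cell line with increasing amounts of a small interfering RNA
(siRNA) drives down the level of its target mRNA, but the shape of that
dose-response curve — and in particular whether silencing *saturates* at
high doses — depends on the kinetics of the RNA-induced silencing complex
(RISC). `rnaikin` is for systems/synthetic biologists who measure knockdown
ratios (target level in treated cells over non-targeting control, by qPCR
or FACS) across a range of siRNA doses and want to ask: *which kinetic law
best explains these data, and with what parameters?*

## The models

The target mRNA `Xm` and its protein `Xp` obey

    dXm/dt = km − dm·Xm − δ(Xm, Xs)
    dXp/dt = kT·Xm − dp·Xp

with the siRNA amount `Xs` held constant over the experiment. Four
candidate laws for the RNAi-induced degradation rate δ are compared:

| model  | δ(Xm, Xs)                               | character                    |
|--------|------------------------------------------|------------------------------|
| model1 | k₁·Xs·Xm                                 | stoichiometric mass action   |
| model2 | k₂·Xs^h₂·Xm                              | mass action + cooperativity  |
| model3 | c₃·k₃h₃·Xs·Xm / (c₃ + k₃h₃·Xm)           | enzymatic (catalytic RISC); Michaelis–Menten in Xm at fixed Xs |
| model4 | d₄·Xs^h₄/(θ₄^h₄ + Xs^h₄)·Xm              | phenomenological Hill; saturates in Xs |

Fitting uses the closed-form steady-state knockdown ratios (treated over
control, so the transcription rate cancels; model3 enters only through the
clustered quantities k₃h₃ and c₃/km), an SE-weighted squared-error
objective, a seeded differential-evolution global search with an L-BFGS-B
polish, errors normalized against the worst model, and leave-one-out
cross-validated prediction error to guard against overfitting. The basal
degradation rate is fixed at dm = ln(2)/40 ≈ 0.0173 min⁻¹ (40-minute mRNA
half-life), never fitted.

## Worked example

Generate a noisy synthetic triplicate experiment from the Hill law on the
standard 14-dose (0–200 pmol per 2 mL well) grid, then fit and compare all
four models:

```r
library(rnaikin)

sh <- shared_rates(dm = 0.0173)
p4 <- model_params("model4", d4 = 8.1e-3, theta4 = 0.105, h4 = 4.47)
ds <- generate_dataset("model4", p4, sh,
                       noise = noise_model(cv = 0.1, n_replicates = 3),
                       seed = 11)

fits <- fit_all_models(ds, sh, fit_options(seed = 1, restarts = 6))
sapply(fits, function(f) f$normalized_error)
#>      model1      model2      model3      model4
#> 0.999999900 0.028913460 1.000000000 0.004191549
```

The worst-fitting model scores exactly 1; here the Hill model (`model4`,
the generating law) fits ~240× better than the mass-action laws, and the
mass-action (`model1`) and enzymatic (`model3`) laws are numerically
indistinguishable — the enzymatic fit runs to the fast-cleavage corner of
its parameter space where it degenerates to mass action. Cross-validation
tells the same story:

```r
loos <- normalize_pe(lapply(names(fits), loo_prediction_error,
                            dataset = ds, shared = sh,
                            options = fit_options(seed = 1, restarts = 4)))
sapply(loos, function(l) l$normalized_pe)
#>      model1      model2      model3      model4
#> 0.999999800 0.122984000 1.000000000 0.009110003
```

Individual fits are classed objects with the usual methods:

```r
fit <- fits$model4
coef(fit)         # d4, theta4, h4
predict(fit, newdata = c(0.05, 0.5, 5))
plot(fit)         # data with error bars + fitted dose-response curve
```

`knockdown_ratio()`, `steady_state_mrna()` and `simulate_timecourse()`
expose the underlying closed forms and the ODE integrator;
`pmol_to_molar()` and `halflife_to_rate()` handle the unit conversions
(200 pmol in 2 mL = 100 nM; a 40-min half-life = 0.0173 min⁻¹). A YAML-
driven pipeline (`run_pipeline()`, wrapped by `inst/scripts/rnaikin.R`)
chains generate → fit → crossval → report for shell use.

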