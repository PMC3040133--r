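# Shared fixtures: the published fitted parameter sets for the EGFP
# experiments and the fixed basal degradation rate dm = 0.0173 min^-1
# (40-minute mRNA half-life).

sh_fixed <- shared_rates(dm = 0.0173)

egfp_mrna_m1 <- model_params("model1", k1 = 1.38e-4)
egfp_mrna_m2 <- model_params("model2", k2 = 5.00e-3, h2 = 0.126)
egfp_mrna_m3 <- model_params("model3", k3h3 = 1.40e-4, c3_over_km = 1.33e3)
egfp_mrna_m4 <- model_params("model4", d4 = 8.1e-3, theta4 = 0.105, h4 = 4.47)
egfp_prot_m4 <- model_params("model4", d4 = 8.6e-3, theta4 = 12.9, h4 = 4.49)

all_params <- function(shared = sh_fixed) {
  list(model1 = egfp_mrna_m1, model2 = egfp_mrna_m2,
       model3 = egfp_mrna_m3, model4 = egfp_mrna_m4)
}

# Small option sets that keep unit tests fast but deterministic.
quick_opts <- function(seed = 1, restarts = 3, ...) {
  fit_options(seed = seed, restarts = restarts, ...)
}

noisefree <- noise_model(cv = 0)

param_names_of <- function(model) rnaikin:::param_names(model)

# Log-uniform draw on [lo, hi]; used for random parameter sweeps.
runif_log <- function(lo, hi) exp(runif(1, log(lo), log(hi)))

# Random but physiologically plausible parameter sets per model (uses the
# caller's RNG stream; seed before use).
random_params <- function(model) {
  switch(model,
    model1 = model_params("model1", k1 = runif_log(1e-5, 1e-2)),
    model2 = model_params("model2", k2 = runif_log(1e-5, 1e-2),
                          h2 = runif(1, 0.2, 3)),
    model3 = model_params("model3", k3h3 = runif_log(1e-5, 1e-2),
                          c3_over_km = runif_log(1, 1e5)),
    model4 = model_params("model4", d4 = runif_log(1e-3, 1e-1),
                          theta4 = runif_log(0.01, 50),
                          h4 = runif(1, 0.5, 6)))
}
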