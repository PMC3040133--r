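#' Shared (non-RNAi) kinetic rates
#'
#' Bundles the four kinetic constants of the basal transcription-translation
#' system: transcription rate `km`, basal mRNA degradation rate `dm`,
#' translation rate `kT` and protein degradation rate `dp`. These rates are
#' common to all four RNAi degradation laws; `dm` is the only one that enters
#' the knockdown ratio, the others cancel or scale out.
#'
#' @param km transcription rate (arbitrary units per minute). Defaults to 1
#'   a.u./min: it cancels in all knockdown ratios.
#' @param dm basal mRNA degradation rate (1/min). Default `log(2)/40`,
#'   i.e. 0.0173 min^-1 for a 40-minute mRNA half-life.
#' @param kT translation rate (1/min).
#' @param dp basal protein degradation rate (1/min). Default `log(2)/1500`
#'   (25 h protein half-life). Cancels in protein knockdown ratios.
#'
#' @return An object of class `shared_rates` (named list of the four rates).
#' @examples
#' shared_rates()               # defaults: 40-min mRNA half-life
#' shared_rates(dm = log(2)/60) # a 1-hour half-life instead
#' @export
shared_rates <- function(km = 1, dm = log(2) / 40, kT = 1, dp = log(2) / 1500) {
  for (nm in c("km", "dm", "kT", "dp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm))
  }
  structure(list(km = km, dm = dm, kT = kT, dp = dp), class = "shared_rates")
}

#' @export
print.shared_rates <- function(x, ...) {
  cat("Shared kinetic rates (a.u., min^-1):\n")
  cat(sprintf("  km = %g  dm = %g  kT = %g  dp = %g\n", x$km, x$dm, x$kT, x$dp))
  invisible(x)
}

# Canonical model identifiers
MODEL_IDS <- c("model1", "model2", "model3", "model4")

#' Validate a model identifier
#'
#' @param model one of `"model1"` (mass-action), `"model2"` (cooperative
#'   mass-action), `"model3"` (enzymatic), `"model4"` (Hill).
#' @return The matched identifier, invisibly usable.
#' @keywords internal
check_model_id <- function(model) {
  if (!is.character(model) || length(model) != 1L || !(model %in% MODEL_IDS))
    stop("'model' must be one of: ", paste(MODEL_IDS, collapse = ", "))
  model
}

#' Construct per-model RNAi degradation parameters
#'
#' Each of the four degradation laws has its own parameter set:
#' \describe{
#'   \item{model1}{`k1` — rate of mRNA-siRNA* complex formation
#'     ((pmol min)^-1); mass-action law \eqn{\delta = k_1 X_s X_m}.}
#'   \item{model2}{`k2` ((pmol^h2 min)^-1) and cooperativity exponent `h2`;
#'     \eqn{\delta = k_2 X_s^{h_2} X_m}. With `h2 = 1` this is model1.}
#'   \item{model3}{clustered enzymatic parameters `k3h3` (product of
#'     complex-formation rate and site count, (pmol min)^-1) and
#'     `c3_over_km` (cleavage/dissociation rate over transcription rate,
#'     a.u.). The unclustered k3, h3, c3 are never represented separately:
#'     the steady-state ratio only identifies these two combinations.}
#'   \item{model4}{Hill law: maximal RNAi degradation rate `d4` (1/min),
#'     half-maximal siRNA amount `theta4` (pmol), Hill coefficient `h4`.}
#' }
#'
#' @param model model identifier, see [check_model_id()] values.
#' @param ... named numeric parameters for that model (see Details).
#' @return Object of class `c("model_params", "<model>_params")`.
#' @examples
#' model_params("model4", d4 = 8.1e-3, theta4 = 0.105, h4 = 4.47)
#' model_params("model1", k1 = 1.38e-4)
#' @export
model_params <- function(model, ...) {
  check_model_id(model)
  p <- list(...)
  want <- param_names(model)
  if (!setequal(names(p), want))
    stop(sprintf("%s requires exactly the parameters: %s", model,
                 paste(want, collapse = ", ")))
  p <- p[want]
  for (nm in want) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single finite positive number", nm))
  }
  structure(c(p, list(model = model)),
            class = c(paste0(model, "_params"), "model_params"))
}

#' Parameter names for each degradation law
#' @param model model identifier.
#' @return Character vector of parameter names, in canonical order.
#' @keywords internal
param_names <- function(model) {
  switch(check_model_id(model),
         model1 = "k1",
         model2 = c("k2", "h2"),
         model3 = c("k3h3", "c3_over_km"),
         model4 = c("d4", "theta4", "h4"))
}

#' @export
print.model_params <- function(x, ...) {
  nm <- param_names(x$model)
  cat(sprintf("RNAi degradation parameters [%s]:\n", x$model))
  cat(paste(sprintf("  %s = %.4g", nm, unlist(x[nm])), collapse = "\n"), "\n")
  invisible(x)
}

# Internal: require a params object matching the model id, or a bare named
# list carrying the right names (convenience for optimizer internals).
match_params <- function(model, params) {
  check_model_id(model)
  if (inherits(params, "model_params")) {
    if (!identical(params$model, model))
      stop(sprintf("parameter object is for '%s', not '%s'", params$model, model))
    return(params)
  }
  do.call(model_params, c(list(model = model), params[param_names(model)]))
}
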