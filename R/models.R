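#' RNAi-induced mRNA degradation rate
#'
#' Evaluates the extra degradation term delta(Xm, Xs) of the chosen kinetic
#' law at mRNA level `xm` and siRNA amount `xs`:
#' \describe{
#'   \item{model1}{\eqn{k_1 X_s X_m} — stoichiometric mass action.}
#'   \item{model2}{\eqn{k_2 X_s^{h_2} X_m} — mass action with cooperativity.}
#'   \item{model3}{\eqn{c_3 k_3 h_3 X_s X_m / (c_3 + k_3 h_3 X_m)} —
#'     enzymatic (catalytic RISC); at fixed `xs` this is Michaelis-Menten in
#'     `xm`. Evaluated in the clustered parametrization (`k3h3`,
#'     `c3_over_km`), which requires `km` from `shared` to recover
#'     \eqn{c_3 = (c_3/k_m) k_m}.}
#'   \item{model4}{\eqn{d_4 X_s^{h_4} / (\theta_4^{h_4} + X_s^{h_4}) \cdot X_m}
#'     — phenomenological Hill law; saturates in `xs` at rate `d4`.}
#' }
#'
#' @param model model identifier (`"model1"` ... `"model4"`).
#' @param params matching [model_params()] object.
#' @param xm mRNA level (a.u.), nonnegative; vectorized.
#' @param xs siRNA amount (pmol), nonnegative; vectorized.
#' @param shared [shared_rates()] object (only `km` is used, by model3).
#' @return Degradation rate (a.u./min), same length as `xm`/`xs` recycled;
#'   zero whenever `xm = 0` or `xs = 0`.
#' @examples
#' sh <- shared_rates()
#' p4 <- model_params("model4", d4 = 8.1e-3, theta4 = 0.105, h4 = 4.47)
#' delta_rate("model4", p4, xm = 1, xs = 0.105, shared = sh)  # d4/2
#' @export
delta_rate <- function(model, params, xm, xs, shared = shared_rates()) {
  params <- match_params(model, params)
  stopifnot(inherits(shared, "shared_rates"))
  if (any(xm < 0) || any(xs < 0))
    stop("'xm' and 'xs' must be nonnegative")
  switch(model,
    model1 = params$k1 * xs * xm,
    model2 = params$k2 * xs^params$h2 * xm,
    model3 = {
      c3 <- params$c3_over_km * shared$km
      a <- params$k3h3
      c3 * a * xs * xm / (c3 + a * xm)
    },
    model4 = {
      h <- params$h4
      params$d4 * xs^h / (params$theta4^h + xs^h) * xm
    })
}

#' Closed-form steady-state mRNA level
#'
#' Solves \eqn{k_m - d_m \tilde X_m - \delta(\tilde X_m, X_s) = 0} for the
#' unique positive equilibrium of each degradation law:
#' models 1, 2 and 4 are rational in `xs`; model3 is the positive root of a
#' quadratic in `xm`. With `xs = 0` every model returns the negative-control
#' equilibrium `km/dm`.
#'
#' @inheritParams delta_rate
#' @param xs siRNA amount (pmol), nonnegative; vectorized.
#' @return Equilibrium mRNA level (a.u.).
#' @examples
#' sh <- shared_rates()
#' steady_state_mrna("model1", model_params("model1", k1 = 1.38e-4), sh, xs = 0)
#' @export
steady_state_mrna <- function(model, params, shared = shared_rates(), xs) {
  params <- match_params(model, params)
  stopifnot(inherits(shared, "shared_rates"))
  if (any(xs < 0)) stop("'xs' must be nonnegative")
  km <- shared$km; dm <- shared$dm
  switch(model,
    model1 = km / (dm + params$k1 * xs),
    model2 = km / (dm + params$k2 * xs^params$h2),
    model3 = {
      a <- params$k3h3
      c3 <- params$c3_over_km * km
      B <- c3 * dm + c3 * a * xs - a * km
      (-B + sqrt(B^2 + 4 * c3 * a * km * dm)) / (2 * a * dm)
    },
    model4 = {
      h <- params$h4; th <- params$theta4^params$h4
      km * (th + xs^h) / (th * dm + (params$d4 + dm) * xs^h)
    })
}

#' Steady-state knockdown ratio (treated / negative control)
#'
#' The steady-state mRNA level under siRNA treatment divided by the
#' negative-control equilibrium `km/dm`. The transcription rate `km` cancels
#' for models 1, 2 and 4; for model3 the ratio depends only on the clustered
#' quantities (`k3h3`, `c3_over_km`) and `dm`:
#' \deqn{r = \frac{-b + \sqrt{b^2 + 4 (c_3/k_m)\, k_3h_3\, d_m}}{2\, k_3h_3},
#'   \quad b = (c_3/k_m) d_m + (c_3/k_m) k_3h_3 X_s - k_3h_3.}
#' The protein-level knockdown ratio is algebraically identical (the gain
#' `kT/dp` cancels between treatment and control).
#'
#' @inheritParams steady_state_mrna
#' @return Ratio in (0, 1]; exactly 1 at `xs = 0`.
#' @examples
#' sh <- shared_rates()
#' p1 <- model_params("model1", k1 = 1.38e-4)
#' knockdown_ratio("model1", p1, sh, xs = c(0, 1, 10, 200))
#' @export
knockdown_ratio <- function(model, params, shared = shared_rates(), xs) {
  params <- match_params(model, params)
  stopifnot(inherits(shared, "shared_rates"))
  if (any(xs < 0)) stop("'xs' must be nonnegative")
  dm <- shared$dm
  switch(model,
    model1 = dm / (dm + params$k1 * xs),
    model2 = dm / (dm + params$k2 * xs^params$h2),
    model3 = {
      a <- params$k3h3
      r <- params$c3_over_km
      b <- r * dm + r * a * xs - a
      (-b + sqrt(b^2 + 4 * r * a * dm)) / (2 * a)
    },
    model4 = {
      h <- params$h4; th <- params$theta4^params$h4
      dm * (th + xs^h) / (th * dm + (params$d4 + dm) * xs^h)
    })
}

#' Steady-state protein level
#'
#' At equilibrium the protein tracks the mRNA with gain `kT/dp`:
#' \eqn{X_p = (k_T/d_p)\,\tilde X_m}. The negative-control protein level is
#' \eqn{(k_T/d_p)(k_m/d_m)}, so protein knockdown ratios equal mRNA
#' knockdown ratios.
#'
#' @param shared [shared_rates()] object.
#' @param xm_eq equilibrium mRNA level (a.u.), nonnegative; vectorized.
#' @return Equilibrium protein level (a.u.).
#' @export
protein_steady_state <- function(shared, xm_eq) {
  stopifnot(inherits(shared, "shared_rates"))
  if (any(xm_eq < 0)) stop("'xm_eq' must be nonnegative")
  shared$kT / shared$dp * xm_eq
}

#' Michaelis-Menten view of the enzymatic law
#'
#' At a fixed siRNA amount the model3 degradation term is a classical
#' Michaelis-Menten rate \eqn{V_m X_m/(K_m + X_m)} with
#' \eqn{V_m = c_3 X_s} and \eqn{K_m = c_3/(k_3 h_3)}. Un-clusters
#' \eqn{c_3 = (c_3/k_m) k_m} using `km` from `shared`.
#'
#' @param params [model_params()] object for `"model3"`.
#' @param shared [shared_rates()] object.
#' @param xs siRNA amount (pmol), nonnegative.
#' @return Named list with elements `Vm` (a.u./min) and `Km` (a.u.).
#' @examples
#' mm <- michaelis_menten_view(
#'   model_params("model3", k3h3 = 1.40e-4, c3_over_km = 1.33e3),
#'   shared_rates(), xs = 1)
#' @export
michaelis_menten_view <- function(params, shared = shared_rates(), xs) {
  params <- match_params("model3", params)
  stopifnot(inherits(shared, "shared_rates"))
  if (any(xs < 0)) stop("'xs' must be nonnegative")
  c3 <- params$c3_over_km * shared$km
  list(Vm = c3 * xs, Km = c3 / params$k3h3)
}
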