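#' Options controlling the global fit
#'
#' @param bounds named list overriding default per-parameter search bounds
#'   (each element a length-2 positive numeric `c(lower, upper)`). Defaults:
#'   rate constants (k1, k2, k3h3, d4) in `[1e-8, 1e2]`, Hill exponents
#'   (h2, h4) in `[0.05, 10]`, `theta4` in `[1e-4, 1e3]` pmol, the clustered
#'   `c3_over_km` in `[1e-8, 1e6]`. All searched on the log10 scale.
#' @param seed integer seed driving every stochastic step of the search.
#' @param restarts independent optimizer runs (best result kept); `>= 1`.
#' @param constrain_h_ge_1 if `TRUE`, Hill exponents are constrained to
#'   `>= 1` (the biologically interpretable regime: at least one siRNA
#'   binding site).
#' @param weighted `TRUE` for SE-weighted least squares, `FALSE` for plain
#'   least squares, or `NULL` (default) to use weights exactly when the
#'   dataset carries positive SEs at every dose.
#' @param pop_size,generations differential-evolution population size
#'   (per free parameter) and generation count; defaults recover
#'   three-parameter Hill fits on 14-dose data reliably.
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(bounds = list(), seed = 1L, restarts = 10L,
                        constrain_h_ge_1 = FALSE, weighted = NULL,
                        pop_size = 12L, generations = 80L) {
  stopifnot(restarts >= 1, pop_size >= 4, generations >= 1)
  for (b in bounds) {
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0) || b[1] >= b[2])
      stop("each bound must be c(lower, upper), finite, positive, lower < upper")
  }
  structure(list(bounds = bounds, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 constrain_h_ge_1 = isTRUE(constrain_h_ge_1),
                 weighted = weighted,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations)),
            class = "fit_options")
}

# Default search box for one model, honoring overrides and the h >= 1
# constraint. Returned as a 2 x d matrix (rows: lower, upper).
default_bounds <- function(model, options) {
  nm <- param_names(model)
  box <- list(k1 = c(1e-8, 1e2), k2 = c(1e-8, 1e2), k3h3 = c(1e-8, 1e2),
              d4 = c(1e-8, 1e2), c3_over_km = c(1e-8, 1e6),
              h2 = c(0.05, 10), h4 = c(0.05, 10),
              theta4 = c(1e-4, 1e3))
  if (options$constrain_h_ge_1) {
    box$h2[1] <- 1
    box$h4[1] <- max(box$h4[1], 1)
  }
  for (p in intersect(names(options$bounds), nm)) box[[p]] <- options$bounds[[p]]
  sapply(nm, function(p) box[[p]])
}

#' Squared-error objective for a vector of model ratios
#'
#' The fitting objective: \eqn{\sum_i ((y^{model}_i - y^{data}_i)/SE_i)^2}
#' when weighted, or the unweighted sum of squares when the data are too
#' noisy for reliable SE estimates. Scaling all SEs by a factor `c` scales
#' the weighted error by `1/c^2`.
#'
#' @param model_ratios model-predicted knockdown ratios, one per dataset dose.
#' @param dataset a [dose_response()] dataset.
#' @param weighted logical; SE-weighting requires every SE positive (an SE
#'   at or below `1e-6` raises an error suggesting unweighted mode).
#' @return Nonnegative error; zero iff the model matches the data exactly.
#' @export
weighted_sse <- function(model_ratios, dataset, weighted = TRUE) {
  stopifnot(inherits(dataset, "dose_response"))
  if (length(model_ratios) != nrow(dataset))
    stop("'model_ratios' length must match the number of doses")
  resid <- model_ratios - dataset$ratio_mean
  if (weighted) {
    se <- dataset$ratio_se
    if (any(!is.finite(se)) || any(se <= 1e-6))
      stop("SE-weighted error needs all standard errors > 1e-6; ",
           "use weighted = FALSE (or supply an SE floor) for this dataset")
    resid <- resid / se
  }
  sum(resid^2)
}

# Objective over log10-parameters for the DE search and polish.
make_objective <- function(model, dataset, shared, weighted) {
  nm <- param_names(model)
  y <- dataset$ratio_mean
  xs <- dataset$dose_pmol
  w <- if (weighted) 1 / dataset$ratio_se else rep(1, length(y))
  function(logp) {
    p <- as.list(10^logp)
    names(p) <- nm
    pred <- switch(model,
      model1 = shared$dm / (shared$dm + p$k1 * xs),
      model2 = shared$dm / (shared$dm + p$k2 * xs^p$h2),
      model3 = {
        a <- p$k3h3; r <- p$c3_over_km; dm <- shared$dm
        b <- r * dm + r * a * xs - a
        (-b + sqrt(b^2 + 4 * r * a * dm)) / (2 * a)
      },
      model4 = {
        th <- p$theta4^p$h4; xh <- xs^p$h4
        shared$dm * (th + xh) / (th * shared$dm + (p$d4 + shared$dm) * xh)
      })
    val <- sum((w * (pred - y))^2)
    if (!is.finite(val)) 1e300 else val
  }
}

# Differential evolution (rand/1/bin) on a box in log10 space.
# Deterministic given the RNG state on entry.
de_minimize <- function(fn, lower, upper, np, generations, f = 0.8, cr = 0.9) {
  d <- length(lower)
  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 3L)
      trial <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

#' Fit one kinetic model to a dose-response dataset
#'
#' Globally minimizes the (optionally SE-weighted) squared error between the
#' model's closed-form steady-state knockdown ratios and the measured
#' ratios, over the model's free parameters. The basal mRNA degradation rate
#' `dm` is fixed (never fitted); the transcription rate never enters the
#' ratios (model3 sees it only through the clustered `c3_over_km`). The
#' search runs `restarts` independent differential-evolution passes on the
#' log10-scaled parameter box, each polished with L-BFGS-B, and keeps the
#' best minimum. Deterministic given `options$seed`.
#'
#' @param model model identifier (`"model1"` ... `"model4"`).
#' @param dataset a [dose_response()] dataset.
#' @param shared [shared_rates()]; only `dm` matters here.
#' @param options a [fit_options()] object.
#' @return Object of class `rnai_fit` with components `model`, `params`
#'   (a [model_params()] object), `raw_error`, `normalized_error` (`NA`
#'   until [compare_models()]), `weighted`, `dataset`, `shared`,
#'   `options`, `convergence`.
#' @examples
#' p1 <- model_params("model1", k1 = 1.38e-4)
#' ds <- generate_dataset("model1", p1, noise = noise_model(cv = 0), seed = 7)
#' fit <- fit_model("model1", ds, options = fit_options(seed = 1, restarts = 4))
#' coef(fit)
#' @export
fit_model <- function(model, dataset, shared = shared_rates(),
                      options = fit_options()) {
  check_model_id(model)
  stopifnot(inherits(dataset, "dose_response"), inherits(options, "fit_options"))
  weighted <- options$weighted
  if (is.null(weighted)) {
    weighted <- has_ses(dataset) && all(dataset$ratio_se > 1e-6)
  } else if (isTRUE(weighted) && (!has_ses(dataset) || any(dataset$ratio_se <= 1e-6))) {
    stop("SE-weighted fitting requested but the dataset has missing or ",
         "near-zero standard errors; use weighted = FALSE")
  }
  fn <- make_objective(model, dataset, shared, weighted)
  box <- default_bounds(model, options)
  lower <- log10(box[1, ]); upper <- log10(box[2, ])
  d <- length(lower)
  np <- max(4L * d, options$pop_size * d %/% 1L, options$pop_size)

  best <- NULL
  for (r in seq_len(options$restarts)) {
    res <- local_seed(options$seed + r - 1L, {
      g <- de_minimize(fn, lower, upper, np = np,
                       generations = options$generations)
      polish <- stats::optim(g$par, fn, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 500, factr = 1e4))
      if (polish$value <= g$value) polish else c(g, list(convergence = 0L))
    })
    if (is.null(best) || res$value < best$value) best <- res
  }
  pars <- as.list(10^best$par)
  names(pars) <- param_names(model)
  structure(list(model = model,
                 params = do.call(model_params, c(list(model = model), pars)),
                 raw_error = best$value,
                 normalized_error = NA_real_,
                 weighted = weighted,
                 dataset = dataset,
                 shared = shared,
                 options = options,
                 convergence = best$convergence),
            class = "rnai_fit")
}

#' Fit all four models and normalize their errors
#'
#' Convenience wrapper: fits each kinetic law to the same dataset with the
#' same options, then sets normalized errors via [compare_models()].
#'
#' @inheritParams fit_model
#' @param models which models to fit (default all four).
#' @return Named list of [fit_model()] results with `normalized_error` set.
#' @export
fit_all_models <- function(dataset, shared = shared_rates(),
                           options = fit_options(), models = MODEL_IDS) {
  fits <- lapply(models, fit_model, dataset = dataset, shared = shared,
                 options = options)
  names(fits) <- models
  if (length(fits) > 1L) compare_models(fits) else fits
}

#' Normalize fit errors across models
#'
#' Divides every model's raw error by the largest raw error among the fits,
#' so the worst model scores exactly 1 and the others are relative to it.
#' Requires one fit per model on the same data.
#'
#' @param fits list of [fit_model()] results, one per distinct model.
#' @return The same list with `normalized_error` filled in.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  ids <- vapply(fits, function(f) f$model, character(1))
  if (anyDuplicated(ids)) stop("duplicate model in 'fits'")
  raw <- vapply(fits, function(f) f$raw_error, numeric(1))
  mx <- max(raw)
  norm <- if (mx == 0) rep(1, length(raw)) else raw / mx  # all-perfect ties
  for (i in seq_along(fits)) fits[[i]]$normalized_error <- norm[i]
  names(fits) <- ids
  fits
}
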