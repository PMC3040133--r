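#' The 14-dose transfection grid
#'
#' The siRNA amounts transfected per 2 mL well in the silencing experiments
#' the generator emulates: 14 doses spanning 0 to 200 pmol.
#'
#' @return Numeric vector of 14 doses (pmol).
#' @export
paper_dose_grid <- function() {
  c(0, 0.001, 0.01, 0.05, 0.1, 0.5, 1, 10, 20, 40, 60, 80, 100, 200)
}

#' Replicate noise model
#'
#' Multiplicative lognormal noise on replicate knockdown ratios. Ratios are
#' positive and fold-change-like, so noise is modeled on the log scale; the
#' lognormal is parameterized to have mean 1 so replicate means are unbiased:
#' `sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2/2`.
#'
#' @param cv coefficient of variation of a single replicate (dimensionless,
#'   `>= 0`). Default 0.1, a visually realistic triplicate spread for qPCR
#'   ratio measurements.
#' @param n_replicates biological replicates per dose (default 3).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.1, n_replicates = 3L) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0)
    stop("'cv' must be a single nonnegative number")
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    stop("'n_replicates' must be a positive integer")
  structure(list(cv = cv, n_replicates = as.integer(n_replicates)),
            class = "noise_model")
}

#' Generate a synthetic dose-response dataset
#'
#' Draws `n_replicates` noisy knockdown ratios per dose from the chosen
#' kinetic law and summarizes them as the experiments would: replicate mean,
#' and standard error = sample SD / sqrt(n). Each replicate is
#' `true_ratio * L` with `L` lognormal, mean 1, coefficient of variation
#' `noise$cv`. With `cv = 0` the means equal the model ratios exactly and
#' all SEs are zero.
#'
#' @inheritParams knockdown_ratio
#' @param doses dose grid in pmol; default [paper_dose_grid()].
#' @param noise a [noise_model()].
#' @param seed integer seed; required for reproducibility.
#' @param level `"mRNA"` or `"protein"` flag carried by the dataset
#'   (protein ratios follow the same formula; the translation gain cancels).
#' @param label dataset label.
#' @return A [dose_response()] dataset; the replicate-level draws are kept
#'   in attribute `replicates` (long data frame: dose_pmol, replicate,
#'   ratio).
#' @examples
#' p4 <- model_params("model4", d4 = 8.1e-3, theta4 = 0.105, h4 = 4.47)
#' ds <- generate_dataset("model4", p4, seed = 1)
#' @export
generate_dataset <- function(model, params, shared = shared_rates(),
                             doses = paper_dose_grid(),
                             noise = noise_model(), seed,
                             level = c("mRNA", "protein"),
                             label = NULL) {
  level <- match.arg(level)
  params <- match_params(model, params)
  stopifnot(inherits(noise, "noise_model"))
  if (missing(seed)) stop("'seed' is required")
  truth <- knockdown_ratio(model, params, shared, xs = doses)
  n <- noise$n_replicates
  reps <- local_seed(seed, {
    if (noise$cv == 0) {
      matrix(rep(truth, each = n), nrow = n)
    } else {
      sdlog <- sqrt(log(1 + noise$cv^2))
      fac <- matrix(stats::rlnorm(n * length(doses),
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = n)
      sweep(fac, 2, truth, `*`)
    }
  })
  means <- colMeans(reps)
  ses <- if (n > 1) apply(reps, 2, stats::sd) / sqrt(n) else rep(0, length(doses))
  if (is.null(label))
    label <- sprintf("synthetic %s (%s, cv=%g, n=%d, seed=%d)",
                     level, model, noise$cv, n, as.integer(seed))
  out <- dose_response(doses, means, ratio_ses = ses, n_replicates = n,
                       level = level, label = label)
  attr(out, "replicates") <- data.frame(
    dose_pmol = rep(doses, each = n),
    replicate = rep(seq_len(n), times = length(doses)),
    ratio = as.vector(reps))
  attr(out, "generator") <- list(model = model, params = params,
                                 noise = noise, seed = as.integer(seed))
  out
}

#' Write replicate-level draws of a synthetic dataset
#'
#' @param dataset a dataset from [generate_dataset()].
#' @param path output CSV path (columns dose_pmol, replicate, ratio).
#' @return `path`, invisibly.
#' @export
write_replicates <- function(dataset, path) {
  reps <- attr(dataset, "replicates")
  if (is.null(reps)) stop("dataset carries no replicate-level draws")
  utils::write.csv(reps, path, row.names = FALSE)
  invisible(path)
}

#' Convert an amount in pmol to a molar concentration
#'
#' @param amount_pmol amount in picomoles (vectorized, nonnegative).
#' @param volume_l well volume in liters (default 2 mL, the transfection
#'   volume of the emulated experiments).
#' @param unit output unit: `"M"`, `"nM"` or `"pM"`.
#' @return Concentration in the requested unit.
#' @examples
#' pmol_to_molar(200, unit = "nM")  # 100 nM
#' pmol_to_molar(0.1, unit = "pM")  # 50 pM
#' @export
pmol_to_molar <- function(amount_pmol, volume_l = 2e-3,
                          unit = c("M", "nM", "pM")) {
  unit <- match.arg(unit)
  if (!is.numeric(volume_l) || length(volume_l) != 1L || volume_l <= 0)
    stop("'volume_l' must be a single positive volume in liters")
  if (any(amount_pmol < 0)) stop("'amount_pmol' must be nonnegative")
  molar <- amount_pmol * 1e-12 / volume_l
  switch(unit, M = molar, nM = molar * 1e9, pM = molar * 1e12)
}

#' First-order rate constant from a half-life
#'
#' @param t_half half-life in minutes (positive).
#' @return Rate `log(2)/t_half` in 1/min. A 40-minute mRNA half-life gives
#'   0.0173 min^-1.
#' @examples
#' halflife_to_rate(40)
#' @export
halflife_to_rate <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0))
    stop("'t_half' must be positive and finite")
  log(2) / t_half
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; seeds must stay below .Machine$integer.max.
local_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
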