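#' Leave-one-out cross-validated prediction error
#'
#' For each dose point in turn, refits the model on the remaining points and
#' scores the prediction at the held-out dose with the same squared-error
#' term used for fitting (SE-weighted when SEs are available and requested).
#' The prediction error (PE) is the average of the held-out errors — a guard
#' against overfitting when comparing models of different complexity.
#'
#' Each fold reuses the seed policy `seed + 1000 * fold` so folds are
#' independent but the whole procedure is reproducible. A fold whose fit
#' fails is flagged and skipped with a warning; the PE then averages the
#' successful folds.
#'
#' @inheritParams fit_model
#' @return Object of class `rnai_loo`: list with `model`, `predicted`
#'   (held-out predictions, one per dose), `fold_errors`,
#'   `prediction_error` (their mean), `normalized_pe` (`NA` until
#'   [normalize_pe()]), `weighted`, `failed_folds`.
#' @examples
#' p1 <- model_params("model1", k1 = 1.38e-4)
#' ds <- generate_dataset("model1", p1, noise = noise_model(cv = 0), seed = 3)
#' loo <- loo_prediction_error("model1", ds,
#'                             options = fit_options(seed = 1, restarts = 2))
#' loo$prediction_error
#' @export
loo_prediction_error <- function(model, dataset, shared = shared_rates(),
                                 options = fit_options()) {
  check_model_id(model)
  stopifnot(inherits(dataset, "dose_response"))
  n <- nrow(dataset)
  if (n < 3L) stop("leave-one-out needs at least 3 dose points")
  weighted <- options$weighted
  if (is.null(weighted)) weighted <- has_ses(dataset) && all(dataset$ratio_se > 1e-6)

  predicted <- rep(NA_real_, n)
  fold_errors <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    train <- dose_response(dataset$dose_pmol[keep], dataset$ratio_mean[keep],
                           ratio_ses = dataset$ratio_se[keep],
                           n_replicates = dataset$n_replicates[keep],
                           level = attr(dataset, "level"),
                           label = attr(dataset, "label"))
    fold_opts <- options
    fold_opts$seed <- options$seed + 1000L * i
    fold_opts$weighted <- weighted
    fit <- tryCatch(fit_model(model, train, shared, fold_opts),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, i)
      warning(sprintf("fold %d fit failed (%s); excluded from PE", i,
                      conditionMessage(fit)))
      next
    }
    pred <- predict(fit, newdata = dataset$dose_pmol[i])
    predicted[i] <- pred
    err <- (pred - dataset$ratio_mean[i])^2
    if (weighted) err <- err / dataset$ratio_se[i]^2
    fold_errors[i] <- err
  }
  structure(list(model = model,
                 predicted = predicted,
                 fold_errors = fold_errors,
                 prediction_error = mean(fold_errors, na.rm = TRUE),
                 normalized_pe = NA_real_,
                 weighted = weighted,
                 failed_folds = failed),
            class = "rnai_loo")
}

#' @export
print.rnai_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out prediction error [%s]%s: %.4g over %d folds\n",
              x$model, if (x$weighted) " (SE-weighted)" else " (unweighted)",
              x$prediction_error, length(x$fold_errors) - length(x$failed_folds)))
  if (is.finite(x$normalized_pe))
    cat(sprintf("  normalized PE: %.3g\n", x$normalized_pe))
  invisible(x)
}

#' Normalize prediction errors across models
#'
#' Divides each model's PE by the largest PE among the results, so the
#' worst-generalizing model scores exactly 1.
#'
#' @param loos list of [loo_prediction_error()] results, one per model.
#' @return The same list with `normalized_pe` filled in.
#' @export
normalize_pe <- function(loos) {
  stopifnot(is.list(loos), length(loos) >= 1)
  ids <- vapply(loos, function(l) l$model, character(1))
  if (anyDuplicated(ids)) stop("duplicate model in 'loos'")
  pe <- vapply(loos, function(l) l$prediction_error, numeric(1))
  mx <- max(pe)
  norm <- if (mx == 0) rep(1, length(pe)) else pe / mx
  for (i in seq_along(loos)) loos[[i]]$normalized_pe <- norm[i]
  names(loos) <- ids
  loos
}
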