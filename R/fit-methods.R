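#' @export
print.rnai_fit <- function(x, ...) {
  cat(sprintf("RNAi dose-response fit [%s]%s\n", x$model,
              if (x$weighted) " (SE-weighted)" else " (unweighted)"))
  nm <- param_names(x$model)
  cat("  ", paste(sprintf("%s = %.3g", nm, unlist(x$params[nm])),
                  collapse = ",  "), "\n", sep = "")
  cat(sprintf("  fit error: %.4g", x$raw_error))
  if (is.finite(x$normalized_error))
    cat(sprintf("  (normalized: %.3g)", x$normalized_error))
  cat("\n")
  invisible(x)
}

#' @export
coef.rnai_fit <- function(object, ...) {
  nm <- param_names(object$model)
  unlist(object$params[nm])
}

#' Predicted knockdown ratios from a fitted model
#'
#' @param object an `rnai_fit` from [fit_model()].
#' @param newdata optional vector of siRNA doses (pmol); defaults to the
#'   fitted dataset's doses.
#' @param ... unused.
#' @return Predicted knockdown ratios.
#' @export
predict.rnai_fit <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$dataset$dose_pmol else newdata
  knockdown_ratio(object$model, object$params, object$shared, xs = xs)
}

#' @export
residuals.rnai_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  r <- predict(object) - object$dataset$ratio_mean
  if (type == "weighted") {
    if (!has_ses(object$dataset))
      stop("dataset has no standard errors; weighted residuals unavailable")
    r <- r / object$dataset$ratio_se
  }
  r
}

#' @export
summary.rnai_fit <- function(object, ...) {
  structure(list(fit = object,
                 n = nrow(object$dataset),
                 rmse = sqrt(mean(residuals(object)^2))),
            class = "summary.rnai_fit")
}

#' @export
print.summary.rnai_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d doses, RMSE of ratios: %.4g\n", x$n, x$rmse))
  invisible(x)
}

#' @export
plot.rnai_fit <- function(x, n_grid = 200, ...) {
  plot(x$dataset, ...)
  d <- x$dataset$dose_pmol
  pos <- d[d > 0]
  grid <- c(0, exp(seq(log(min(pos) / 10), log(max(pos)), length.out = n_grid)))
  gx <- ifelse(grid == 0, min(pos) / 10, grid)
  graphics::lines(gx, predict(x, newdata = grid), col = 2)
  graphics::legend("bottomleft", bty = "n",
                   legend = sprintf("%s fit", x$model), col = 2, lty = 1)
  invisible(x)
}

#' Simulate synthetic datasets from a fitted model
#'
#' Draws new dose-response datasets from the fitted kinetic law using the
#' package's replicate-noise generator — a parametric bootstrap of the
#' experimental design.
#'
#' @param object an `rnai_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed (first dataset uses `seed`, then `seed + 1`, ...).
#' @param noise a [noise_model()]; default cv 0.1, triplicates.
#' @param ... unused.
#' @return A list of `nsim` [dose_response()] datasets.
#' @export
simulate.rnai_fit <- function(object, nsim = 1, seed = 1L,
                              noise = noise_model(), ...) {
  lapply(seq_len(nsim) - 1L, function(i)
    generate_dataset(object$model, object$params, object$shared,
                     doses = object$dataset$dose_pmol, noise = noise,
                     seed = seed + i, level = attr(object$dataset, "level")))
}
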