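#' Construct a dose-response dataset
#'
#' A validated container for knockdown measurements: siRNA doses (pmol per
#' well), mean knockdown ratios (treated/control), their standard errors and
#' replicate counts, plus a flag for the measurement level (mRNA by qPCR or
#' protein by FACS).
#'
#' @param doses nonnegative siRNA doses in pmol; must be unique. Sorted on
#'   construction.
#' @param ratio_means positive mean knockdown ratios, one per dose.
#' @param ratio_ses standard errors of the ratio means (nonnegative), or
#'   `NULL`/`NA` when unavailable (disables SE-weighted fitting).
#' @param n_replicates positive integer replicate count per dose (scalar
#'   recycled or vector).
#' @param level `"mRNA"` or `"protein"`.
#' @param label free-text dataset label.
#' @return Object of class `dose_response` (a data frame with columns
#'   `dose_pmol`, `ratio_mean`, `ratio_se`, `n_replicates` and attributes
#'   `level`, `label`).
#' @examples
#' dose_response(doses = c(0, 1, 10), ratio_means = c(1, 0.6, 0.4),
#'               ratio_ses = c(0.02, 0.03, 0.04))
#' @export
dose_response <- function(doses, ratio_means, ratio_ses = NULL,
                          n_replicates = 3L, level = c("mRNA", "protein"),
                          label = "") {
  level <- match.arg(level)
  n <- length(doses)
  if (n < 1L) stop("at least one dose is required")
  if (any(!is.finite(doses)) || any(doses < 0)) stop("doses must be finite and nonnegative")
  if (anyDuplicated(doses)) stop("doses must be unique")
  if (length(ratio_means) != n) stop("'ratio_means' length must match 'doses'")
  if (any(!is.finite(ratio_means)) || any(ratio_means <= 0))
    stop("'ratio_means' must be finite and positive")
  if (is.null(ratio_ses)) ratio_ses <- rep(NA_real_, n)
  if (length(ratio_ses) == 1L) ratio_ses <- rep(ratio_ses, n)
  if (length(ratio_ses) != n) stop("'ratio_ses' length must match 'doses'")
  if (any(!is.na(ratio_ses) & ratio_ses < 0)) stop("'ratio_ses' must be nonnegative")
  if (length(n_replicates) == 1L) n_replicates <- rep(n_replicates, n)
  if (length(n_replicates) != n) stop("'n_replicates' length must match 'doses'")
  if (any(n_replicates < 1) || any(n_replicates != round(n_replicates)))
    stop("'n_replicates' must be positive integers")

  ord <- order(doses)
  out <- data.frame(dose_pmol = doses[ord],
                    ratio_mean = ratio_means[ord],
                    ratio_se = as.numeric(ratio_ses)[ord],
                    n_replicates = as.integer(n_replicates)[ord])
  structure(out, level = level, label = label,
            class = c("dose_response", "data.frame"))
}

#' Does a dataset carry usable standard errors?
#' @param dataset a [dose_response()] object.
#' @return `TRUE` if every dose has a finite SE.
#' @export
has_ses <- function(dataset) {
  stopifnot(inherits(dataset, "dose_response"))
  all(is.finite(dataset$ratio_se))
}

#' @export
print.dose_response <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("Dose-response dataset (%s level%s): %d doses, %g-%g pmol\n",
              attr(x, "level"), if (nzchar(lbl)) paste0(", '", lbl, "'") else "",
              nrow(x), min(x$dose_pmol), max(x$dose_pmol)))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' @export
plot.dose_response <- function(x, ...,
                               xlab = "siRNA dose (pmol)",
                               ylab = "knockdown ratio (treated/control)") {
  d <- x$dose_pmol
  eps <- min(d[d > 0]) / 10  # place dose 0 on the log axis
  dx <- ifelse(d == 0, eps, d)
  graphics::plot(dx, x$ratio_mean, log = "x", xlab = xlab, ylab = ylab,
                 ylim = c(0, max(1, x$ratio_mean + x$ratio_se, na.rm = TRUE)),
                 pch = 19, ...)
  if (has_ses(x))
    graphics::arrows(dx, x$ratio_mean - x$ratio_se, dx,
                     x$ratio_mean + x$ratio_se,
                     angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Read a dose-response dataset from CSV
#'
#' Expects columns `dose_pmol`, `ratio_mean` and optionally `ratio_se` and
#' `n_replicates`. A missing `ratio_se` column yields a dataset without SEs
#' (SE-weighted fitting is then unavailable; a notice is emitted).
#'
#' @param path CSV file path.
#' @param level measurement level flag, `"mRNA"` or `"protein"`.
#' @param label dataset label; defaults to the file name.
#' @return A [dose_response()] object.
#' @export
read_dataset <- function(path, level = c("mRNA", "protein"), label = NULL) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_pmol", "ratio_mean")
  if (!all(need %in% names(df)))
    stop("dataset must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$dose_pmol) | df$dose_pmol < 0 |
                 !is.finite(df$ratio_mean) | df$ratio_mean <= 0)
  if (length(bad))
    stop(sprintf("malformed dataset row(s) at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path))  # +1 for header
  if (anyDuplicated(df$dose_pmol))
    stop("duplicate doses in ", path)
  ses <- if ("ratio_se" %in% names(df)) df$ratio_se else NULL
  if (is.null(ses))
    message("no 'ratio_se' column in ", basename(path),
            ": SE-weighted fitting disabled for this dataset")
  nrep <- if ("n_replicates" %in% names(df)) df$n_replicates else 3L
  dose_response(df$dose_pmol, df$ratio_mean, ratio_ses = ses,
                n_replicates = nrep, level = level,
                label = if (is.null(label)) basename(path) else label)
}

#' Write a dose-response dataset to CSV
#'
#' @param dataset a [dose_response()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "dose_response"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}
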