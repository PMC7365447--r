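#' Mean relative error
#'
#' `(1/m) * sum(|pred - actual| / actual)`, the objective minimized by the
#' genetic algorithm (as a fraction, not a percentage). The actual values
#' must be nonzero; PBF is strictly positive in valid data.
#'
#' @param pred,actual numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
mean_relative_error <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop("pred and actual differ in length", call. = FALSE)
  }
  if (length(pred) < 1L) stop("need at least one value", call. = FALSE)
  z <- which(actual == 0)
  if (length(z)) {
    stop("actual value is zero at row(s) ", paste(z, collapse = ", "),
         "; relative error undefined", call. = FALSE)
  }
  mean(abs(pred - actual) / actual)
}

#' Mean square error, as-printed form
#'
#' `(1/n) * sum((pred - mean(pred))^2)`: the dispersion of the predictions
#' about their own mean (the population variance of `pred`). This is the
#' published form of the model's mean square error; note that it measures
#' prediction spread, not prediction error. Use [mse_conventional()] for
#' the usual mean squared prediction error.
#'
#' @param pred numeric vector of predictions.
#' @return non-negative scalar.
#' @export
mse_printed <- function(pred) {
  if (length(pred) < 1L) stop("need at least one value", call. = FALSE)
  mean((pred - mean(pred))^2)
}

#' Mean squared prediction error
#'
#' `(1/n) * sum((pred - actual)^2)`, the conventional mean squared error
#' against observed values.
#'
#' @param pred,actual numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
mse_conventional <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop("pred and actual differ in length", call. = FALSE)
  }
  mean((pred - actual)^2)
}

#' Pearson correlation between predictions and observations
#'
#' @param pred,actual numeric vectors of equal length (at least 2), both
#'   non-constant.
#' @return correlation in \[-1,1\].
#' @export
pearson_corr <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    stop("pred and actual differ in length", call. = FALSE)
  }
  if (length(pred) < 2L) stop("need at least two values", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0) {
    stop("correlation undefined: zero variance in pred or actual", call. = FALSE)
  }
  stats::cov(pred, actual) / sqrt(stats::var(pred) * stats::var(actual))
}

#' Evaluate predictions against observed PBF
#'
#' Bundles the package's evaluation metrics into one report: mean relative
#' error (fraction), the as-printed mean square error (prediction
#' dispersion), the conventional mean squared prediction error, and the
#' Pearson correlation.
#'
#' @param pred,actual numeric vectors of equal length.
#' @return an object of class `"pbf_evaluation"`: a list with elements
#'   `mean_relative_error`, `mse_printed`, `mse_conventional`, `pearson_r`
#'   and `n`.
#' @export
evaluate_predictions <- function(pred, actual) {
  structure(list(mean_relative_error = mean_relative_error(pred, actual),
                 mse_printed = mse_printed(pred),
                 mse_conventional = mse_conventional(pred, actual),
                 pearson_r = pearson_corr(pred, actual),
                 n = length(pred)),
            class = "pbf_evaluation")
}

#' @export
print.pbf_evaluation <- function(x, digits = 4, ...) {
  cat("PBF prediction evaluation (n = ", x$n, ")\n", sep = "")
  cat("  mean relative error: ", format(x$mean_relative_error, digits = digits),
      " (", format(100 * x$mean_relative_error, digits = digits), "%)\n", sep = "")
  cat("  MSE (as printed, prediction dispersion):",
      format(x$mse_printed, digits = digits), "\n")
  cat("  MSE (conventional):",
      format(x$mse_conventional, digits = digits), "\n")
  cat("  Pearson r:", format(x$pearson_r, digits = digits), "\n")
  invisible(x)
}

#' @export
as.data.frame.pbf_evaluation <- function(x, ...) {
  data.frame(mean_relative_error = x$mean_relative_error,
             mse_printed = x$mse_printed,
             mse_conventional = x$mse_conventional,
             pearson_r = x$pearson_r,
             n = x$n)
}
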