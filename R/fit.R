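#' Fit the linear PBF model with a genetic algorithm
#'
#' Fits the percentage-body-fat model
#' `PBF = w1 G + w2 A + w3 W + w4 H + w5 R1R2 + w6 R2R3 + w7 R4R5 +
#' w8 R2 + w9 H2/R2 + b`
#' (or the same form over any chosen candidate features) by minimizing the
#' mean relative prediction error with the configured genetic-algorithm
#' strategy (see [ga_config()] and [evolve()]).
#'
#' @param data a cohort data frame with a `PBF` column, or a
#'   `"candidate_features"` object with a target.
#' @param features names of the model features among the candidate
#'   columns; defaults to the reference nine-feature set
#'   [pbf_reference_features()].
#' @param config a [ga_config()] object.
#' @param condition passed to [evolve()]; keep TRUE unless you need the
#'   genes to be the raw-scale coefficients.
#' @return an object of class `"pbf_model"` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' spec <- synthetic_spec(n_samples = 120, seed = 7)
#' cohort <- generate_cohort(spec)
#' cfg <- ga_config(max_generations = 40, seed = 7)
#' fit <- fit_pbf(cohort, config = cfg)
#' coef(fit)
#' @export
fit_pbf <- function(data, features = pbf_reference_features(),
                    config = ga_config(), condition = TRUE) {
  feats <- if (inherits(data, "candidate_features")) data
           else build_candidate_features(data)
  if (is.null(feats$target)) {
    stop("training data has no PBF column", call. = FALSE)
  }
  missing_f <- setdiff(features, feats$feature_names)
  if (length(missing_f)) {
    stop("feature(s) not in the candidate table: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  X <- feats$values[, features, drop = FALSE]
  F <- feats$target
  res <- evolve(X, F, config, condition = condition)
  fitted_vals <- as.vector(X %*% res$omega) + res$b
  structure(list(coefficients = stats::setNames(res$omega, features),
                 b = res$b,
                 feature_names = features,
                 fitness = res$fitness,
                 object = res$object,
                 trace = res$trace,
                 terminated_by = res$terminated_by,
                 generations = res$generations,
                 config = config,
                 n = nrow(X),
                 fitted.values = fitted_vals,
                 y = F,
                 call = match.call()),
            class = "pbf_model")
}

#' @export
print.pbf_model <- function(x, digits = 6, ...) {
  cat("Linear PBF model solved by", x$config$strategy, "\n")
  cat("Coefficients:\n")
  print(signif(c(x$coefficients, b = x$b), digits))
  cat("Fitness:", format(x$fitness, digits = digits),
      " (mean relative error ", format(100 * x$object, digits = 4), "%)\n",
      sep = "")
  cat("Stopped by ", x$terminated_by, " after ", x$generations,
      " generations (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.pbf_model <- function(object, ...) {
  c(object$coefficients, b = object$b)
}

#' Predict PBF for new samples
#'
#' @param object a fitted `"pbf_model"`.
#' @param newdata a cohort data frame, a `"candidate_features"` object, or
#'   a numeric matrix/data frame whose columns include the model features.
#'   Omitted: returns fitted values.
#' @param ... unused.
#' @return numeric vector of predicted PBF (%).
#' @export
predict.pbf_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "candidate_features")) {
    V <- newdata$values
  } else if (is.data.frame(newdata) && all(.cohort_cols %in% names(newdata))) {
    V <- build_candidate_features(newdata)$values
  } else {
    V <- as.matrix(newdata)
  }
  missing_f <- setdiff(object$feature_names, colnames(V))
  if (length(missing_f)) {
    stop("newdata lacks model feature(s): ",
         paste(missing_f, collapse = ", "),
         "; available: ", paste(utils::head(colnames(V), 15), collapse = ", "),
         if (ncol(V) > 15) ", ...", call. = FALSE)
  }
  X <- V[, object$feature_names, drop = FALSE]
  as.vector(X %*% object$coefficients) + object$b
}

#' @export
fitted.pbf_model <- function(object, ...) object$fitted.values

#' @export
residuals.pbf_model <- function(object, ...) object$y - object$fitted.values

#' @export
summary.pbf_model <- function(object, ...) {
  ev <- evaluate_predictions(object$fitted.values, object$y)
  structure(list(model = object, training_evaluation = ev),
            class = "summary.pbf_model")
}

#' @export
print.summary.pbf_model <- function(x, ...) {
  print(x$model)
  cat("\nTraining-set evaluation:\n")
  print(x$training_evaluation)
  invisible(x)
}

#' Plot the fitness trace of a fitted PBF model
#'
#' Best and mean population fitness per generation.
#'
#' @param x a fitted `"pbf_model"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pbf_model <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$generation, tr$best_fitness, type = "l",
                 xlab = "generation", ylab = "fitness",
                 ylim = range(c(tr$best_fitness, tr$mean_fitness)), ...)
  graphics::lines(tr$generation, tr$mean_fitness, lty = 2)
  graphics::legend("bottomright", legend = c("best", "mean"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Persist a fitted PBF model as plain text
#'
#' Writes a key/value text file holding the feature names, coefficients
#' (17 significant digits), constant term and run metadata.
#'
#' @param model a `"pbf_model"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pbf_model <- function(model, path) {
  lines <- c(
    paste0("features: ", paste(model$feature_names, collapse = ",")),
    paste0("omega: ", paste(sprintf("%.17g", model$coefficients), collapse = " ")),
    paste0("b: ", sprintf("%.17g", model$b)),
    paste0("fitness: ", sprintf("%.17g", model$fitness)),
    paste0("object: ", sprintf("%.17g", model$object)),
    paste0("strategy: ", model$config$strategy),
    paste0("seed: ", if (is.null(model$config$seed)) "NA" else model$config$seed),
    paste0("terminated_by: ", model$terminated_by),
    paste0("generations: ", model$generations),
    paste0("n: ", model$n))
  writeLines(lines, path)
  invisible(path)
}

#' Read a persisted PBF model
#'
#' @param path file written by [write_pbf_model()].
#' @return a `"pbf_model"` (without the fitness trace or training data).
#' @export
read_pbf_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = ": "),
                                 character(1)),
                          vapply(kv, `[[`, character(1), 1L))
  features <- strsplit(vals[["features"]], ",", fixed = TRUE)[[1]]
  omega <- as.numeric(strsplit(vals[["omega"]], " ", fixed = TRUE)[[1]])
  if (length(omega) != length(features)) {
    stop("corrupt model file: coefficient count differs from feature count",
         call. = FALSE)
  }
  seed <- suppressWarnings(as.integer(vals[["seed"]]))
  structure(list(coefficients = stats::setNames(omega, features),
                 b = as.numeric(vals[["b"]]),
                 feature_names = features,
                 fitness = as.numeric(vals[["fitness"]]),
                 object = as.numeric(vals[["object"]]),
                 trace = NULL,
                 terminated_by = vals[["terminated_by"]],
                 generations = as.integer(vals[["generations"]]),
                 config = ga_config(strategy = vals[["strategy"]],
                                    seed = if (is.na(seed)) NULL else seed),
                 n = as.integer(vals[["n"]]),
                 fitted.values = NULL,
                 y = NULL,
                 call = NULL),
            class = "pbf_model")
}
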