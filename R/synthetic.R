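#' Specification of a synthetic BIA cohort
#'
#' Describes a cohort generated with known ground truth: demographics in
#' the ranges of a hospital BIA study population (age 9--84 years, height
#' 149--190 cm, weight 38.4--121.4 kg), eight segmental impedances with
#' bilaterally similar limbs and trunk segments an order of magnitude
#' smaller than limbs, and PBF produced by a known instance of the linear
#' reference model plus Gaussian noise.
#'
#' The default coefficients are chosen to mimic BIA practice: males get a
#' lower PBF (negative gender coefficient), PBF rises with age, weight,
#' impedance products and the height-squared-over-resistance index, and
#' falls with height; their magnitudes put the noiseless PBF around
#' 15--40%.
#'
#' @param n_samples cohort size (default 220, at least 10).
#' @param true_omega nine coefficients of the generating model, in the
#'   order of [pbf_reference_features()]; all within the GA gene range.
#' @param true_b constant term of the generating model.
#' @param noise_sd standard deviation of the Gaussian PBF noise, in %
#'   units (default 1.5, a realistic residual scale for BIA equations).
#' @param n_noise_features extra irrelevant covariates for planted-feature
#'   tasks.
#' @param redundancy add near-duplicate copies of the driver columns in
#'   planted-feature tasks.
#' @param seed optional integer seed.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples = 220,
                           true_omega = c(G = -6, A = 0.05, W = 0.3,
                                          H = -0.35, R1R2 = 3e-4,
                                          R2R3 = -2e-4, R4R5 = 5e-3,
                                          R2 = 0.35, `H2/R2` = 0.015),
                           true_b = 35.5,
                           noise_sd = 1.5,
                           n_noise_features = 0,
                           redundancy = FALSE,
                           seed = NULL) {
  if (n_samples < 10) stop("n_samples must be at least 10", call. = FALSE)
  if (length(true_omega) != 9L) {
    stop("true_omega must have nine coefficients", call. = FALSE)
  }
  if (any(abs(c(true_omega, true_b)) > 100)) {
    stop("true coefficients must lie within the gene range [-100, 100]",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 true_omega = stats::setNames(as.numeric(true_omega),
                                              pbf_reference_features()),
                 true_b = true_b, noise_sd = noise_sd,
                 n_noise_features = as.integer(n_noise_features),
                 redundancy = isTRUE(redundancy), seed = seed),
            class = "synthetic_spec")
}

# Demographics and impedances only; PBF is added by the caller.
generate_covariates <- function(n) {
  male <- stats::rbinom(n, 1, 0.5) == 1
  gender <- ifelse(male, "M", "F")
  age <- sample(9:84, n, replace = TRUE)
  height <- ifelse(male, stats::rnorm(n, 172, 7), stats::rnorm(n, 159, 6))
  height <- pmin(pmax(height, 149), 190)
  bmi <- stats::rnorm(n, 24.5, 3.2)
  weight <- pmin(pmax(bmi * (height / 100)^2, 38.4), 121.4)
  # limbs ~ 200-400 ohm, females higher; bilateral pairs within ~3%
  upper <- stats::rlnorm(n, log(ifelse(male, 255, 320)), 0.10)
  R1 <- upper * exp(stats::rnorm(n, 0, 0.012))
  R3 <- upper * exp(stats::rnorm(n, 0, 0.012))
  lower <- upper * 0.80 * exp(stats::rnorm(n, 0, 0.05))
  R7 <- lower * exp(stats::rnorm(n, 0, 0.012))
  R8 <- lower * exp(stats::rnorm(n, 0, 0.012))
  # trunk segments ~ 20-35 ohm
  trunk <- stats::rlnorm(n, log(ifelse(male, 21.5, 23)), 0.07)
  R2 <- trunk
  R4 <- trunk * 1.025 * exp(stats::rnorm(n, 0, 0.015))
  R5 <- trunk * 1.07 * exp(stats::rnorm(n, 0, 0.02))
  R6 <- trunk * 1.30 * exp(stats::rnorm(n, 0, 0.04))
  data.frame(gender = gender, age = age, weight = weight, height = height,
             R1 = R1, R2 = R2, R3 = R3, R4 = R4, R5 = R5, R6 = R6,
             R7 = R7, R8 = R8, stringsAsFactors = FALSE)
}

#' Generate a synthetic BIA cohort with known ground truth
#'
#' Draws demographics and segmental impedances as specified, then sets
#' `PBF` from the generating linear model on the reference features plus
#' Gaussian noise, clipped to \[3, 60\]%. Specs whose model clips more
#' than 1% of samples are rejected as infeasible. The generating
#' coefficients are attached as attribute `"ground_truth"`.
#'
#' @param spec a [synthetic_spec()] object.
#' @return a `"pbf_cohort"` data frame with a `PBF` column.
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must be a synthetic_spec object", call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  df <- generate_covariates(spec$n_samples)
  feats <- build_candidate_features(as_pbf_cohort(df, identifier = "synthetic"))
  X <- feats$values[, pbf_reference_features(), drop = FALSE]
  pbf <- as.vector(X %*% spec$true_omega) + spec$true_b
  if (spec$noise_sd > 0) pbf <- pbf + stats::rnorm(spec$n_samples, 0, spec$noise_sd)
  clipped <- pbf < 3 | pbf > 60
  if (mean(clipped) > 0.01) {
    stop("infeasible spec: generating model clips ",
         round(100 * mean(clipped), 1), "% of PBF values outside [3, 60]",
         call. = FALSE)
  }
  df$PBF <- pmin(pmax(pbf, 3), 60)
  out <- as_pbf_cohort(df, identifier = "synthetic")
  attr(out, "ground_truth") <- list(true_omega = spec$true_omega,
                                    true_b = spec$true_b,
                                    noise_sd = spec$noise_sd,
                                    seed = spec$seed)
  out
}

#' Generate a planted-feature selection task
#'
#' Builds the full candidate feature table of a synthetic cohort and makes
#' the target a linear function of a known subset of candidate columns
#' (the drivers, on standardized scale) plus Gaussian noise. Optionally
#' appends `n_noise_features` independent standard-normal columns and,
#' with `redundancy`, a near-duplicate copy of each driver (1% relative
#' jitter). Ground truth (drivers, duplicates, coefficients) is attached
#' as attribute `"ground_truth"` for selection-recovery experiments.
#'
#' @param spec a [synthetic_spec()] object; `noise_sd`,
#'   `n_noise_features`, `redundancy` and `seed` are honoured.
#' @param drivers candidate columns that drive the target.
#' @param driver_coef coefficient per driver on the standardized scale
#'   (default 2.5% PBF per standard deviation).
#' @return a `"candidate_features"` object with a target.
#' @export
generate_planted_feature_task <- function(spec = synthetic_spec(),
                                          drivers = c("A", "W", "R1R2"),
                                          driver_coef = 2.5) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must be a synthetic_spec object", call. = FALSE)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  df <- generate_covariates(n)
  feats <- build_candidate_features(as_pbf_cohort(df, identifier = "planted"))
  bad <- setdiff(drivers, feats$feature_names)
  if (length(bad)) stop("unknown driver column(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  coef <- rep_len(driver_coef, length(drivers))
  Z <- scale(feats$values[, drivers, drop = FALSE])
  target <- 27 + as.vector(Z %*% coef)
  if (spec$noise_sd > 0) target <- target + stats::rnorm(n, 0, spec$noise_sd)
  V <- feats$values
  if (spec$n_noise_features > 0) {
    noise <- matrix(stats::rnorm(n * spec$n_noise_features), n)
    colnames(noise) <- paste0("noise", seq_len(spec$n_noise_features))
    V <- cbind(V, noise)
  }
  duplicates <- character(0)
  if (spec$redundancy) {
    dup <- feats$values[, drivers, drop = FALSE] *
      matrix(1 + stats::rnorm(n * length(drivers), 0, 0.01), n)
    colnames(dup) <- paste0("dup_", drivers)
    duplicates <- colnames(dup)
    V <- cbind(V, dup)
  }
  structure(list(values = V,
                 feature_names = colnames(V),
                 target = target,
                 distance_features = feats$distance_features),
            ground_truth = list(drivers = drivers,
                                duplicates = duplicates,
                                driver_coef = coef,
                                noise_features =
                                  if (spec$n_noise_features > 0)
                                    paste0("noise", seq_len(spec$n_noise_features))
                                  else character(0),
                                seed = spec$seed),
            class = "candidate_features")
}
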