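#' Weights of the combined sample-similarity distance
#'
#' The combined distance between two samples is
#' `C = alpha * D + beta * S`, where `D` is the min-max normalized Euclidean
#' distance between their parameter vectors and `S = 1 - |r|` is the
#' morphological distance (one minus the absolute Pearson correlation of the
#' two parameter profiles). `alpha + beta` must equal 1. The defaults
#' alpha = 1/3, beta = 2/3 weight profile shape twice as heavily as numeric
#' distance, which suits cohorts where bilaterally similar limb impedances
#' make profile shape informative.
#'
#' @param alpha weight of the numeric (normalized Euclidean) distance.
#' @param beta weight of the morphological distance.
#' @return an object of class `"similarity_params"`.
#' @export
similarity_params <- function(alpha = 1 / 3, beta = 2 / 3) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha < 0 || beta < 0) {
    stop("alpha and beta must be non-negative numbers", call. = FALSE)
  }
  if (abs(alpha + beta - 1) > 1e-12) {
    stop("alpha + beta must equal 1 (got ", alpha + beta, ")", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "similarity_params")
}

#' Euclidean distance between two parameter vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 1L) stop("vectors must have length >= 1", call. = FALSE)
  sqrt(sum((x - y)^2))
}

#' Min-max normalize a raw distance matrix
#'
#' Maps every off-diagonal distance to \[0,1\] by
#' `(d - min) / (max - min)`, the minimum and maximum taken globally over
#' all off-diagonal entries; the minimum maps to 0 and the maximum to 1.
#' The diagonal is set to 0. If all off-diagonal distances are equal the
#' matrix is degenerate and all normalized distances are defined as 0, with
#' a warning.
#'
#' @param d square symmetric matrix of raw distances.
#' @return matrix of the same shape with entries in \[0,1\].
#' @export
normalize_distances <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  off <- d[row(d) != col(d)]
  if (length(off) == 0L) stop("need at least two samples", call. = FALSE)
  lo <- min(off)
  hi <- max(off)
  if (hi == lo) {
    warning("all off-diagonal distances are equal; normalized distances set to 0")
    out <- matrix(0, nrow(d), ncol(d))
    dimnames(out) <- dimnames(d)
    return(out)
  }
  out <- (d - lo) / (hi - lo)
  diag(out) <- 0
  pmax(pmin(out, 1), 0)
}

#' Morphological distance between two parameter vectors
#'
#' One minus the absolute Pearson correlation of the two profiles:
#' `S = 1 - |r|`, in \[0,1\]. Both perfectly correlated and perfectly
#' anti-correlated profiles have distance 0 (the same shape up to sign). If
#' either vector has zero variance the correlation is undefined and the
#' distance falls back to 1 (maximally dissimilar), with a warning.
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return morphological distance in \[0,1\].
#' @export
morphological_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors differ in length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 2L) stop("vectors must have length >= 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a parameter vector; morphological distance set to 1")
    return(1)
  }
  1 - abs(stats::cor(x, y))
}

#' Combine numeric and morphological distances
#'
#' @param D normalized Euclidean distance in \[0,1\].
#' @param S morphological distance in \[0,1\].
#' @param params a [similarity_params()] object.
#' @return `alpha * D + beta * S`.
#' @export
combined_distance <- function(D, S, params = similarity_params()) {
  if (!inherits(params, "similarity_params")) params <- do.call(similarity_params, params)
  if (any(D < 0 | D > 1) || any(S < 0 | S > 1)) {
    stop("D and S must lie in [0, 1]", call. = FALSE)
  }
  params$alpha * D + params$beta * S
}

#' Combined sample-similarity distance matrix
#'
#' Computes the full pairwise combined distance over the rows of a
#' parameter matrix: per-column z-scoring (optional but recommended because
#' the parameters mix cm, kg and ohm scales), raw Euclidean distances,
#' global min-max normalization, morphological distances from row-wise
#' Pearson correlations, and the weighted combination.
#'
#' @param X numeric matrix, one row per sample.
#' @param params a [similarity_params()] object.
#' @param standardize z-score columns before computing distances
#'   (default TRUE). Constant columns are left at zero.
#' @return symmetric matrix of combined distances with zero diagonal.
#' @export
combined_distance_matrix <- function(X, params = similarity_params(),
                                     standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two samples", call. = FALSE)
  if (ncol(X) < 2L) {
    stop("need at least two parameter columns for the morphological distance",
         call. = FALSE)
  }
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  }
  D <- normalize_distances(as.matrix(stats::dist(X)))
  rv <- apply(X, 1, stats::sd)
  if (any(rv == 0)) {
    warning("zero-variance parameter vector(s); their morphological distances set to 1")
  }
  S <- 1 - abs(suppressWarnings(stats::cor(t(X))))
  S[is.na(S)] <- 1
  S[rv == 0, ] <- 1
  S[, rv == 0] <- 1
  diag(S) <- 0
  C <- combined_distance(D, S, params)
  diag(C) <- 0
  C
}
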