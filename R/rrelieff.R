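# Weight update from the three accumulators; kept separate so the formula
# can be exercised directly on hand-set counts.
rrelieff_weight_from_counts <- function(n_dc, n_da, n_dcda, m) {
  if (n_dc <= 0) {
    stop("target appears constant over the probed neighbourhoods (N_dC = 0)",
         call. = FALSE)
  }
  if (m - n_dc <= 0) {
    stop("degenerate accumulators: m - N_dC must be positive", call. = FALSE)
  }
  n_dcda / n_dc - (n_da - n_dcda) / (m - n_dc)
}

#' RReliefF feature weights with the combined similarity distance
#'
#' Ranks every candidate feature by how well its differences track target
#' (PBF) differences among near neighbours. Neighbours are found under the
#' combined similarity distance (normalized Euclidean plus morphological,
#' see [combined_distance_matrix()]) computed over the first-order
#' parameter columns of the table. For each of `m_iterations` probe samples
#' the `k_neighbors` nearest neighbours contribute, with uniform weight
#' 1/k, to three accumulators: `N_dC` (target differences), `N_dA[A]`
#' (feature differences) and `N_dCdA[A]` (joint differences). Differences
#' are absolute differences scaled to \[0,1\] by the feature's (and
#' target's) training-set range. The weight of feature A is
#' `W[A] = N_dCdA[A]/N_dC - (N_dA[A] - N_dCdA[A])/(m - N_dC)`.
#'
#' @param features a `"candidate_features"` object with a target.
#' @param k_neighbors number of nearest neighbours per probe (default 10).
#' @param m_iterations number of probe samples, drawn without replacement;
#'   default all samples.
#' @param similarity a [similarity_params()] object.
#' @param standardize z-score the distance-basis columns before computing
#'   the similarity distance (default TRUE). Disable to apply the distance
#'   formulas to the raw parameter values.
#' @param seed optional integer seed for the probe draw.
#' @return an object of class `"feature_weights"`: a data frame with
#'   columns `feature` and `weight`, sorted by decreasing weight, with the
#'   accumulators attached as attributes.
#' @export
rrelieff_weights <- function(features, k_neighbors = 10, m_iterations = NULL,
                             similarity = similarity_params(),
                             standardize = TRUE, seed = NULL) {
  if (!inherits(features, "candidate_features")) {
    stop("features must be a candidate_features object", call. = FALSE)
  }
  y <- features$target
  if (is.null(y)) stop("candidate feature table has no target (PBF)", call. = FALSE)
  V <- features$values
  n <- nrow(V)
  if (k_neighbors < 1 || k_neighbors >= n) {
    stop("k_neighbors must be in [1, n_samples - 1]", call. = FALSE)
  }
  if (is.null(m_iterations)) m_iterations <- n
  if (m_iterations < 1 || m_iterations > n) {
    stop("m_iterations must be in [1, n_samples] (sampling without replacement)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  basis <- V[, intersect(features$distance_features, colnames(V)), drop = FALSE]
  C <- combined_distance_matrix(basis, similarity, standardize = standardize)

  y_range <- max(y) - min(y)
  if (y_range == 0) stop("target is constant; weights are undefined", call. = FALSE)
  f_range <- apply(V, 2, function(v) max(v) - min(v))
  f_range[f_range == 0] <- 1  # constant features get zero diffs anyway

  probes <- sample.int(n, m_iterations, replace = FALSE)
  p <- ncol(V)
  n_dc <- 0
  n_da <- numeric(p)
  n_dcda <- numeric(p)
  for (i in probes) {
    ord <- order(C[i, -i])
    nb <- seq_len(n)[-i][ord[seq_len(k_neighbors)]]
    d_y <- abs(y[i] - y[nb]) / y_range
    d_f <- abs(sweep(V[nb, , drop = FALSE], 2, V[i, ], "-"))
    d_f <- sweep(d_f, 2, f_range, "/")
    w <- 1 / k_neighbors
    n_dc <- n_dc + sum(d_y) * w
    n_da <- n_da + colSums(d_f) * w
    n_dcda <- n_dcda + colSums(d_f * d_y) * w
  }
  W <- rrelieff_weight_from_counts(n_dc, n_da, n_dcda, m_iterations)
  ord <- order(W, decreasing = TRUE)
  structure(data.frame(feature = colnames(V)[ord], weight = W[ord],
                       row.names = NULL, check.names = FALSE),
            N_dC = n_dc, N_dA = stats::setNames(n_da, colnames(V)),
            N_dCdA = stats::setNames(n_dcda, colnames(V)),
            m = m_iterations,
            class = c("feature_weights", "data.frame"))
}

#' Keep features whose weight exceeds a threshold
#'
#' @param weights a `"feature_weights"` object.
#' @param sigma weight threshold; features with weight strictly greater
#'   than `sigma` are kept. The default 0 drops features whose weight is
#'   non-positive, the usual sign of irrelevance for Relief-family weights.
#' @return character vector of feature names in decreasing-weight order.
#' @export
threshold_filter <- function(weights, sigma = 0) {
  if (!inherits(weights, "feature_weights")) {
    stop("weights must be a feature_weights object", call. = FALSE)
  }
  keep <- weights$feature[weights$weight > sigma]
  if (length(keep) == 0L) {
    stop("no feature weight exceeds sigma = ", sigma,
         "; lower the threshold", call. = FALSE)
  }
  as.character(keep)
}
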