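# Equal-frequency discretization into at most n_bins levels. Ties can
# collapse bins; at least two distinct levels are required downstream.
discretize_ef <- function(x, n_bins) {
  if (length(unique(x)) <= n_bins) return(match(x, sort(unique(x))))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Plug-in mutual information between two columns
#'
#' Continuous columns are discretized into `n_bins` equal-frequency bins;
#' columns with at most `n_bins` distinct values are used as-is. Returns
#' the plug-in estimate of mutual information in nats.
#'
#' @param f,c numeric vectors of equal length.
#' @param n_bins number of equal-frequency bins (default 8).
#' @return mutual information in nats (non-negative).
#' @export
mutual_information <- function(f, c, n_bins = 8) {
  if (length(f) != length(c)) {
    stop("columns differ in length (", length(f), " vs ", length(c), ")",
         call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  fd <- discretize_ef(as.numeric(f), n_bins)
  cd <- discretize_ef(as.numeric(c), n_bins)
  joint <- table(fd, cd) / length(f)
  pf <- rowSums(joint)
  pc <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pf, pc)[nz]))
}

# Greedy mRMR score of candidate fi given the already-selected set.
mrmr_score <- function(rel_i, red_i, redundancy_weight = 1) {
  if (length(red_i) == 0L) return(rel_i)
  rel_i - redundancy_weight * mean(red_i)
}

# 5-fold cross-validated accuracy of a 1-NN classifier on the selected
# columns, target discretized into n_classes equal-frequency classes.
# This operationalizes the S_r stop rule for a continuous target.
selection_accuracy <- function(V, sel, cls, folds = 5) {
  X <- V[, sel, drop = FALSE]
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2, colMeans(X), "-"), 2, sdv, "/")
  n <- nrow(X)
  fold <- rep(seq_len(folds), length.out = n)
  correct <- 0L
  for (k in seq_len(folds)) {
    te <- which(fold == k)
    tr <- which(fold != k)
    pred <- class::knn(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                       cl = factor(cls[tr]), k = 1)
    correct <- correct + sum(as.character(pred) == as.character(cls[te]))
  }
  correct / n
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection over a pre-filtered feature list: the first
#' pick maximizes mutual information with the target; each subsequent pick
#' maximizes relevance minus the mean mutual information with the features
#' already selected. Selection stops when the cross-validated accuracy
#' trace satisfies `S_r >= S_(r+1)` (the r+1-th feature no longer helps) or
#' when `max_features` is reached. Accuracy is the 5-fold cross-validated
#' accuracy of a 1-nearest-neighbour classifier on the target discretized
#' into `n_classes` equal-frequency classes. Ties are broken by the
#' position of the feature in the candidate table (lowest column index
#' wins), so the result does not depend on the order of `fprime`.
#'
#' @param fprime character vector of candidate feature names (for example
#'   the output of [threshold_filter()]).
#' @param features the `"candidate_features"` table holding the columns
#'   and the target.
#' @param n_bins equal-frequency bins for mutual-information estimation.
#' @param n_classes equal-frequency classes for the accuracy stop rule.
#' @param max_features cap on the number of selected features (default:
#'   no cap beyond `length(fprime)`).
#' @param folds cross-validation folds for the stop rule (default 5).
#' @param redundancy_weight weight of the redundancy penalty (default 1;
#'   0 reduces the selection to descending relevance order).
#' @return an object of class `"selected_features"`: list with `names`
#'   (selection order), `accuracies` (the S_r trace) and `relevance`.
#' @export
mrmr_select <- function(fprime, features, n_bins = 8, n_classes = 4,
                        max_features = NULL, folds = 5,
                        redundancy_weight = 1) {
  if (!inherits(features, "candidate_features")) {
    stop("features must be a candidate_features object", call. = FALSE)
  }
  y <- features$target
  if (is.null(y)) stop("candidate feature table has no target (PBF)", call. = FALSE)
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  fprime <- as.character(fprime)
  if (length(fprime) == 0L) stop("fprime is empty", call. = FALSE)
  unknown <- setdiff(fprime, features$feature_names)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  # canonical order: position in the candidate table (deterministic ties)
  fprime <- features$feature_names[sort(match(fprime, features$feature_names))]
  V <- features$values
  if (length(fprime) < 2L) {
    warning("fewer than 2 candidate features; returning them unchanged")
    return(structure(list(names = fprime, accuracies = NA_real_,
                          relevance = NULL),
                     class = "selected_features"))
  }
  if (is.null(max_features)) max_features <- length(fprime)
  max_features <- min(max_features, length(fprime))

  rel <- vapply(fprime, function(f) mutual_information(V[, f], y, n_bins),
                numeric(1))
  cls <- discretize_ef(y, n_classes)

  selected <- character(0)
  remaining <- fprime
  acc <- numeric(0)
  # cache pairwise MI among candidates as needed
  red <- matrix(NA_real_, length(fprime), length(fprime),
                dimnames = list(fprime, fprime))
  repeat {
    if (length(selected) == 0L) {
      scores <- rel[remaining]
    } else {
      scores <- vapply(remaining, function(f) {
        for (s in selected) {
          if (is.na(red[f, s])) {
            red[f, s] <<- red[s, f] <<- mutual_information(V[, f], V[, s], n_bins)
          }
        }
        mrmr_score(rel[[f]], red[f, selected], redundancy_weight)
      }, numeric(1))
    }
    pick <- remaining[which.max(scores)]  # first max = lowest column index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    acc <- c(acc, selection_accuracy(V, selected, cls, folds))
    r <- length(selected)
    if (r >= 2L && acc[r - 1L] >= acc[r]) {
      # S_r >= S_(r+1): the last pick did not help; stop at r features
      selected <- selected[seq_len(r - 1L)]
      break
    }
    if (r >= max_features || length(remaining) == 0L) break
  }
  structure(list(names = selected, accuracies = acc,
                 relevance = rel),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat("Selected features (", length(x$names), "):\n  ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  if (!all(is.na(x$accuracies))) {
    cat("Accuracy trace S_r:",
        paste(round(x$accuracies, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full feature-selection pipeline
#'
#' Composes [build_candidate_features()], [rrelieff_weights()],
#' [threshold_filter()] and [mrmr_select()]: candidate expansion, RReliefF
#' ranking under the combined similarity distance, weight thresholding and
#' mRMR reduction.
#'
#' @param cohort a cohort data frame with a PBF column.
#' @param sigma RReliefF weight threshold (default 0).
#' @param k_neighbors,m_iterations,similarity,standardize,seed passed to
#'   [rrelieff_weights()].
#' @param n_bins,n_classes,max_features,folds passed to [mrmr_select()].
#' @return a `"selected_features"` object with the RReliefF weight table
#'   attached as attribute `"weights"` and the thresholded list as
#'   `"fprime"`.
#' @export
select_features <- function(cohort, sigma = 0, k_neighbors = 10,
                            m_iterations = NULL,
                            similarity = similarity_params(),
                            standardize = TRUE, seed = NULL,
                            n_bins = 8, n_classes = 4, max_features = NULL,
                            folds = 5) {
  feats <- if (inherits(cohort, "candidate_features")) cohort
           else build_candidate_features(cohort)
  if (is.null(feats$target)) {
    stop("cohort has no PBF column; feature selection needs the target",
         call. = FALSE)
  }
  w <- rrelieff_weights(feats, k_neighbors = k_neighbors,
                        m_iterations = m_iterations, similarity = similarity,
                        standardize = standardize, seed = seed)
  fprime <- threshold_filter(w, sigma)
  out <- mrmr_select(fprime, feats, n_bins = n_bins, n_classes = n_classes,
                     max_features = max_features, folds = folds)
  attr(out, "weights") <- w
  attr(out, "fprime") <- fprime
  out
}
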