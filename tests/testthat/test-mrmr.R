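test_that("mutual information matches hand computations", {
  # joint counts ((5,0),(0,5)) over 10 samples
  f <- c(rep(0, 5), rep(1, 5))
  expect_equal(mutual_information(f, f, n_bins = 2), log(2))
  # identity: MI equals the entropy of the discretized column
  x <- as.numeric(1:32)
  expect_equal(mutual_information(x, x, n_bins = 8), log(8))
  # independence: near zero at large n
  set.seed(1)
  a <- rnorm(4000); b <- rnorm(4000)
  expect_lt(mutual_information(a, b), 0.05)
  expect_error(mutual_information(1:3, 1:4), "length")
  expect_error(mutual_information(1:3, 1:3, n_bins = 1), "n_bins")
})

test_that("every greedy mRMR step agrees with an exhaustive re-evaluation", {
  set.seed(11)
  n <- 150
  z <- rnorm(n)
  V <- cbind(f1 = z + rnorm(n, 0, 0.3),
             f2 = z + rnorm(n, 0, 0.4),
             f3 = rnorm(n),
             f4 = rnorm(n),
             f5 = z + rnorm(n, 0, 1),
             f6 = rnorm(n),
             f7 = 0.5 * z + rnorm(n),
             f8 = rnorm(n),
             f9 = rnorm(n),
             f10 = rnorm(n))
  y <- z + rnorm(n, 0, 0.2)
  cf <- make_cf(V, target = y)
  sel <- mrmr_select(colnames(V), cf, max_features = 6)
  # brute-force oracle: recompute the greedy criterion at every step
  chosen <- character(0)
  for (step in seq_along(sel$names)) {
    remaining <- setdiff(colnames(V), chosen)
    scores <- vapply(remaining, function(f) {
      rel <- mutual_information(V[, f], y)
      if (length(chosen) == 0L) return(rel)
      red <- vapply(chosen, function(s) mutual_information(V[, f], V[, s]),
                    numeric(1))
      rel - mean(red)
    }, numeric(1))
    best <- remaining[which.max(scores)]
    expect_identical(sel$names[step], best)
    chosen <- c(chosen, best)
  }
})

test_that("the redundancy penalty rejects a duplicate in favour of new information", {
  set.seed(2)
  n <- 200
  z <- rnorm(n)
  w <- rnorm(n)
  V <- cbind(strong = z,
             copy = z * (1 + rnorm(n, 0, 0.01)),
             weak = w)
  y <- z + 0.6 * w
  cf <- make_cf(V, target = y)
  sel <- mrmr_select(colnames(V), cf, max_features = 2)
  expect_true(sel$names[1] %in% c("strong", "copy"))
  expect_identical(sel$names[2], "weak")
  expect_equal(sum(sel$names %in% c("strong", "copy")), 1L)
})

test_that("with the redundancy term disabled, selection is descending relevance", {
  set.seed(3)
  n <- 120
  V <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- 2 * V[, "c"] + V[, "a"] + 0.5 * V[, "d"] + rnorm(n, 0, 0.3)
  cf <- make_cf(V, target = y)
  sel <- mrmr_select(colnames(V), cf, max_features = 4, redundancy_weight = 0)
  rel <- vapply(colnames(V), function(f) mutual_information(V[, f], y),
                numeric(1))
  expect_identical(sel$names,
                   names(sort(rel, decreasing = TRUE))[seq_along(sel$names)])
})

test_that("selection order is invariant to the order of the filtered list", {
  set.seed(4)
  n <- 100
  V <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- V[, "b"] + 0.5 * V[, "a"] + rnorm(n, 0, 0.2)
  cf <- make_cf(V, target = y)
  s1 <- mrmr_select(c("a", "b", "c"), cf, max_features = 3)
  s2 <- mrmr_select(c("c", "b", "a"), cf, max_features = 3)
  expect_identical(s1$names, s2$names)
})

test_that("degenerate inputs are handled", {
  cf <- make_cf(cbind(a = rnorm(30)), target = rnorm(30))
  expect_warning(sel <- mrmr_select("a", cf), "fewer than 2")
  expect_identical(sel$names, "a")
  expect_error(mrmr_select(character(0), cf), "empty")
  expect_error(mrmr_select("zz", cf), "unknown")
})
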