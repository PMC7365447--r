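test_that("generation is deterministic under a seed and respects printed ranges", {
  spec <- synthetic_spec(n_samples = 60, seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$age >= 9 & a$age <= 84))
  expect_true(all(a$height >= 149 & a$height <= 190))
  expect_true(all(a$weight >= 38.4 & a$weight <= 121.4))
  expect_true(all(a$PBF >= 3 & a$PBF <= 60))
  expect_true(all(as.matrix(a[, paste0("R", 1:8)]) > 0))
})

test_that("trunk impedances are an order of magnitude below limb impedances", {
  co <- generate_cohort(synthetic_spec(n_samples = 100, seed = 22))
  limbs <- rowMeans(co[, c("R1", "R3", "R7", "R8")])
  trunk <- rowMeans(co[, c("R2", "R4", "R5", "R6")])
  expect_true(all(limbs > 5 * trunk))
  # second-order features stay strictly positive
  feats <- build_candidate_features(co)
  second <- setdiff(feats$feature_names, c("G", "A", "W", "H"))
  expect_true(all(feats$values[, second] > 0))
})

test_that("noise-free cohorts reproduce the generating model exactly", {
  spec <- synthetic_spec(n_samples = 50, noise_sd = 0, seed = 23)
  co <- generate_cohort(spec)
  gt <- attr(co, "ground_truth")
  feats <- build_candidate_features(co)
  X <- feats$values[, pbf_reference_features()]
  pred <- as.vector(X %*% gt$true_omega) + gt$true_b
  # no clipping events in a valid spec, so the identity is exact
  expect_true(all(pred > 3 & pred < 60))
  expect_equal(co$PBF, pred, tolerance = 1e-12)
})

test_that("a 220-person cohort has a plausible sex split", {
  co <- generate_cohort(synthetic_spec(n_samples = 220, seed = 24))
  n_m <- sum(co$gender == "M")
  # Bernoulli(1/2): 110 +- 3 binomial SDs covers the 96/124 pattern
  expect_true(n_m >= 88 && n_m <= 132)
})

test_that("bilateral limb impedances agree within a few percent", {
  ratios <- vapply(1:50, function(s) {
    co <- generate_cohort(synthetic_spec(n_samples = 60, seed = 300 + s))
    mean(co$R1 / co$R3)
  }, numeric(1))
  expect_gte(mean(ratios), 0.97)
  expect_lte(mean(ratios), 1.03)
})

test_that("infeasible generating models are rejected", {
  expect_error(generate_cohort(synthetic_spec(n_samples = 100, true_b = 95,
                                              seed = 25)),
               "infeasible")
  expect_error(synthetic_spec(n_samples = 5), "at least 10")
  expect_error(synthetic_spec(true_omega = c(200, rep(0, 8))), "gene range")
})

test_that("planted tasks append noise and near-duplicate columns as requested", {
  spec <- synthetic_spec(n_samples = 80, n_noise_features = 4,
                         redundancy = TRUE, seed = 26)
  task <- generate_planted_feature_task(spec)
  gt <- attr(task, "ground_truth")
  expect_equal(gt$noise_features, paste0("noise", 1:4))
  expect_equal(gt$duplicates, paste0("dup_", gt$drivers))
  expect_true(all(c(gt$noise_features, gt$duplicates) %in% task$feature_names))
  # duplicates are nearly perfect copies
  for (i in seq_along(gt$drivers)) {
    expect_gt(stats::cor(task$values[, gt$drivers[i]],
                         task$values[, gt$duplicates[i]]), 0.99)
  }
  # noise columns stay out of the neighbour-distance basis
  expect_false(any(gt$noise_features %in% task$distance_features))
  # without extras the table is the plain candidate table
  plain <- generate_planted_feature_task(synthetic_spec(n_samples = 80, seed = 26))
  expect_equal(ncol(plain$values), 64)
  expect_false(is.null(plain$target))
})
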