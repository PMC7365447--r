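test_that("the packaged test-set fixture reads with the printed values", {
  co <- table3_cohort()
  expect_s3_class(co, "pbf_cohort")
  expect_equal(nrow(co), 20)
  expect_equal(co$gender[1], "F")
  expect_equal(co$age[1], 60)
  expect_equal(co$weight[1], 59.5)
  expect_equal(co$height[1], 162)
  expect_equal(co$PBF[1], 31.1)
  expect_equal(co$R2[1], 23.4)
})

test_that("the PBF column is optional and schema errors name the column", {
  co <- table3_cohort()
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(co[, setdiff(names(co), "PBF")], tmp, row.names = FALSE)
  nopbf <- read_cohort(tmp)
  expect_false("PBF" %in% names(nopbf))

  utils::write.csv(co[, setdiff(names(co), "R4")], tmp, row.names = FALSE)
  expect_error(read_cohort(tmp), "R4")

  bad <- co
  bad$R3 <- as.character(bad$R3)
  bad$R3[7] <- "abc"
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_cohort(tmp), "R3.*7")
})

test_that("cohort validation enforces the physiological invariants", {
  co <- as.data.frame(table3_cohort())
  bad <- co; bad$R5[3] <- -1
  expect_error(as_pbf_cohort(bad), "R5.*positive")
  bad <- co; bad$height[2] <- 0
  expect_error(as_pbf_cohort(bad), "height")
  bad <- co; bad$gender[4] <- "X"
  expect_error(as_pbf_cohort(bad), "gender")
  expect_error(as_pbf_cohort(co[0, ]), "empty")
})

test_that("gender coding is the fixed M=1/F=0 convention", {
  expect_identical(encode_gender(c("M", "F", "M")), c(1, 0, 1))
  expect_error(encode_gender("X"), "invalid gender")
})

test_that("candidate features have the documented 64 columns and values", {
  co <- table3_cohort()
  feats <- build_candidate_features(co)
  expect_equal(dim(feats$values), c(20, 64))
  expect_equal(length(feats$feature_names), 64)
  # every model feature is a candidate column
  expect_true(all(pbf_reference_features() %in% feats$feature_names))
  # hand arithmetic on the printed values of sample 1 (H = 162, R2 = 23.4,
  # R3 = 297.6)
  expect_equal(unname(feats$values[1, "H2/R2"]), 162^2 / 23.4)
  expect_equal(unname(feats$values[1, "R2R3"]), 23.4 * 297.6)
  expect_equal(unname(feats$values[1, "R12"]), 307^2)
  expect_equal(unname(feats$values[1, "1/R6"]), 1 / 30.5)
  t2 <- build_candidate_features(table2_cohort())
  expect_equal(unname(t2$values[1, "R1R2"]), 253.9 * 20.1)
  expect_equal(unname(t2$values[1, "R1R2"]), 5103.39)
})

test_that("a single-sample cohort yields a 1 x 64 table and extras pass through", {
  co <- as.data.frame(table3_cohort())[1, ]
  feats <- build_candidate_features(co)
  expect_equal(dim(feats$values), c(1, 64))
  fx <- build_candidate_features(co, extra = data.frame(smoker = 1))
  expect_equal(dim(fx$values), c(1, 65))
  expect_true("smoker" %in% fx$feature_names)
})

test_that("candidate feature construction is deterministic", {
  co <- table3_cohort()
  a <- build_candidate_features(co)
  b <- build_candidate_features(co)
  expect_identical(a$values, b$values)
})

test_that("write/read round trip reproduces numeric fields exactly", {
  spec <- synthetic_spec(n_samples = 15, seed = 5)
  co <- generate_cohort(spec)
  tmp <- tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  for (cl in c("age", "weight", "height", paste0("R", 1:8), "PBF")) {
    expect_identical(back[[cl]], co[[cl]], label = cl)
  }
})
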