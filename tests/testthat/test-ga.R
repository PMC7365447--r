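test_that("configuration validation catches invalid settings", {
  expect_error(ga_config(M = 0), "M must be")
  expect_error(ga_config(s = 2), "s must be")
  expect_error(ga_config(M = 97, s = 8, strategy = "MAGA"), "divisible")
  expect_s3_class(ga_config(M = 97, s = 8, strategy = "AGA"), "ga_config")
  expect_error(ga_config(gene_range = c(5, -5)), "increasing")
  expect_error(ga_config(k3 = 1.5), "k3")
})

test_that("population initialization is seeded and respects the gene range", {
  cfg <- ga_config(M = 96, seed = 7)
  p1 <- init_population(cfg)
  p2 <- init_population(cfg)
  expect_identical(p1$genes, p2$genes)
  expect_equal(dim(p1$genes), c(96, 10))
  expect_true(all(p1$genes >= -100 & p1$genes <= 100))
  expect_equal(p1$generation, 1L)
})

test_that("fitness follows the 1/(1 + mean relative error) transform", {
  X <- matrix(rnorm(30), 10, 3)
  F <- runif(10, 15, 40)
  # constant model predicting exactly: object 0, fit 1
  expect_equal(evaluate_fitness(c(0, 0, 0, 5), X, rep(5, 10)), 1)
  # object = 1 when predictions double the actuals
  expect_equal(evaluate_fitness(c(0, 0, 0, 10), X, rep(5, 10)), 0.5)
  # shared implementation with mean_relative_error
  w2 <- c(1, -2, 0.5, 3)
  pred <- as.vector(X %*% w2[1:3]) + w2[4]
  expect_equal(evaluate_fitness(w2, X, F),
               1 / (1 + mean_relative_error(pred, F)))
  expect_warning(f0 <- evaluate_fitness(w2, matrix(Inf, 10, 3), F),
                 "non-finite")
  expect_equal(f0, 0)
  expect_error(evaluate_fitness(1:3, X, F), "length")
})

test_that("roulette probabilities are proportional to fitness and sum to 1", {
  expect_equal(roulette_probabilities(rep(2, 4)), rep(0.25, 4))
  expect_equal(roulette_probabilities(c(3, 1)), c(0.75, 0.25))
  set.seed(1)
  p <- roulette_probabilities(runif(50))
  expect_equal(sum(p), 1)
  expect_warning(pz <- roulette_probabilities(rep(0, 5)), "zero")
  expect_equal(pz, rep(0.2, 5))
  expect_error(roulette_probabilities(c(-1, 2)), "non-negative")
})

test_that("the grouped selection operator keeps elites, discards the worst group", {
  set.seed(2)
  cfg <- ga_config(M = 16, s = 8)
  fit <- seq(0.95, 0.05, length.out = 16)
  pop <- make_population(16, fitness = fit)
  sel <- improved_select(pop, cfg)
  expect_equal(nrow(sel$genes), 16)
  # two elites pass unchanged, in fitness order
  expect_identical(sel$genes[1:2, ], pop$genes[1:2, ])
  expect_identical(attr(sel, "elite_rows"), 1:2)
  # the worst group (rows 15, 16) contributes nothing
  for (r in 15:16) {
    expect_false(any(apply(sel$genes, 1, function(g) all(g == pop$genes[r, ]))))
  }
  # the 14 drawn rows all come from the middle (rows 3..14)
  mid <- pop$genes[3:14, , drop = FALSE]
  for (r in 3:16) {
    expect_true(any(apply(mid, 1, function(g) all(g == sel$genes[r, ]))))
  }
})

test_that("selection of a uniform population returns M copies", {
  cfg <- ga_config(M = 8, s = 4)
  pop <- structure(list(genes = matrix(1, 8, 3), fitness = rep(0.5, 8),
                        generation = 1L), class = "pbf_population")
  sel <- improved_select(pop, cfg)
  expect_true(all(sel$genes == 1))
  expect_equal(dim(sel$genes), c(8, 3))
})

test_that("single-elite retention keeps the best and never breeds the worst", {
  set.seed(3)
  fit <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  pop <- make_population(5, fitness = fit)
  sel <- optimal_retention_select(pop)
  expect_equal(nrow(sel$genes), 5)
  expect_identical(sel$genes[1, ], pop$genes[1, ])
  worst <- pop$genes[5, ]
  expect_false(any(apply(sel$genes, 1, function(g) all(g == worst))))
})

test_that("crossover respects its probability and the blend geometry", {
  cfg <- ga_config()
  parents <- rbind(c(1, 2, 3), c(7, 8, 9))
  set.seed(4)
  # pc forced to 0: identical children
  expect_identical(adaptive_crossover(parents, c(0.5, 0.6), 0.9, 0.5, cfg,
                                      pc = 0), parents)
  # a parent at the population maximum gets pc 0 under the adaptive rule
  expect_identical(adaptive_crossover(parents, c(0.9, 0.5), 0.9, 0.5, cfg),
                   parents)
  # blend children stay within the extended per-gene interval
  for (i in 1:50) {
    ch <- adaptive_crossover(parents, c(0.3, 0.4), 0.9, 0.5, cfg, pc = 1)
    span <- abs(parents[1, ] - parents[2, ])
    lo <- pmin(parents[1, ], parents[2, ]) - cfg$blx_alpha * span
    hi <- pmax(parents[1, ], parents[2, ]) + cfg$blx_alpha * span
    expect_true(all(ch[1, ] >= lo - 1e-12 & ch[1, ] <= hi + 1e-12))
    expect_true(all(ch[2, ] >= lo - 1e-12 & ch[2, ] <= hi + 1e-12))
  }
})

test_that("mutation respects its probability and the binomial expectation", {
  cfg <- ga_config()
  g <- seq(-5, 5, length.out = 10)
  set.seed(5)
  expect_identical(adaptive_mutation(g, 0.5, 0.9, 0.5, cfg, pm = 0), g)
  m1 <- adaptive_mutation(g, 0.5, 0.9, 0.5, cfg, pm = 1)
  expect_true(all(m1 >= -100 & m1 <= 100))
  expect_true(all(m1 != g))
  # mean number of mutated genes ~ Binomial(10, pm)
  pm <- 0.3
  n_trials <- 2000
  total <- 0L
  for (i in seq_len(n_trials)) {
    total <- total + sum(adaptive_mutation(g, 0.5, 0.9, 0.5, cfg, pm = pm) != g)
  }
  expected <- 10 * pm
  se <- sqrt(10 * pm * (1 - pm) / n_trials)
  expect_lt(abs(total / n_trials - expected), 3 * se)
})

test_that("evolve terminates at the generation cap and is reproducible", {
  spec <- synthetic_spec(n_samples = 40, seed = 6)
  co <- generate_cohort(spec)
  feats <- build_candidate_features(co)
  X <- feats$values[, pbf_reference_features()]
  cfg <- ga_config(M = 24, s = 8, max_generations = 10,
                   termination_epsilon = 0, seed = 9)
  r1 <- evolve(X, co$PBF, cfg)
  expect_equal(r1$generations, 10)
  expect_equal(r1$terminated_by, "max_generations")
  expect_equal(nrow(r1$trace), 10)
  r2 <- evolve(X, co$PBF, cfg)
  expect_identical(r1$omega, r2$omega)
  expect_identical(r1$trace, r2$trace)
})

test_that("the elitist strategy never lets best fitness decrease", {
  spec <- synthetic_spec(n_samples = 40, seed = 8)
  co <- generate_cohort(spec)
  feats <- build_candidate_features(co)
  X <- feats$values[, pbf_reference_features()]
  cfg <- ga_config(M = 24, s = 8, max_generations = 40,
                   termination_epsilon = 0, seed = 10)
  r <- evolve(X, co$PBF, cfg)
  expect_true(all(diff(r$trace$best_fitness) >= 0))
})

test_that("rank-deficient feature matrices are rejected under conditioning", {
  X <- cbind(a = 1:20, b = 2 * (1:20))
  expect_error(evolve(X, runif(20, 10, 30), ga_config(M = 8, s = 4)),
               "rank-deficient")
})
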