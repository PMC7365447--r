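#' Genetic-algorithm configuration
#'
#' Hyperparameters for the three optimizer strategies. `"GA"` is a plain
#' real-coded genetic algorithm (fixed crossover/mutation probabilities,
#' pure roulette selection). `"AGA"` adds the adaptive probabilities
#' `pc = k1 (f_max - f') / (f_max - f_avg)` for parents at or above the
#' population mean fitness (else `k2`), and similarly `pm` with `k3`/`k4`,
#' so fit individuals are disturbed less. `"MAGA"` further replaces the
#' selection step by the grouped operator of [improved_select()]: the
#' population is sorted into `s` fitness groups; the top group passes to
#' the next generation untouched, the bottom group is discarded, and the
#' middle groups are roulette-sampled.
#'
#' @param M population size (default 96; must be divisible by `s` for
#'   strategy `"MAGA"`).
#' @param s number of fitness groups (default 8, at least 3 so the middle
#'   groups are non-empty).
#' @param max_generations iteration cap (default 400).
#' @param gene_range closed interval for every gene (default c(-100, 100)).
#' @param strategy one of `"MAGA"`, `"AGA"`, `"GA"`.
#' @param k1,k2 adaptive crossover constants (defaults 0.9, 0.9).
#' @param k3,k4 adaptive mutation constants (defaults 0.1, 0.1).
#' @param pc_fixed,pm_fixed fixed probabilities for strategy `"GA"`
#'   (defaults 0.8, 0.05).
#' @param blx_alpha extension of the blend crossover beyond the parent
#'   interval (default 0.5, the classic BLX-0.5).
#' @param gauss_frac fraction of mutations that take a Gaussian step scaled
#'   by the fit-group gene spread; the rest take a log-uniform step of up
#'   to a tenth of the gene range (default 0.5).
#' @param termination_epsilon stop once the best objective (mean relative
#'   error) is at or below this (default 0.01).
#' @param seed optional integer seed; one seeded generator drives the whole
#'   run.
#' @return an object of class `"ga_config"`.
#' @export
ga_config <- function(M = 96, s = 8, max_generations = 400,
                      gene_range = c(-100, 100),
                      strategy = c("MAGA", "AGA", "GA"),
                      k1 = 0.9, k2 = 0.9, k3 = 0.1, k4 = 0.1,
                      pc_fixed = 0.8, pm_fixed = 0.05,
                      blx_alpha = 0.5, gauss_frac = 0.5,
                      termination_epsilon = 0.01, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.numeric(M) || length(M) != 1L || M < 2 || M != round(M)) {
    stop("M must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(s) || s < 3 || s != round(s)) {
    stop("s must be an integer >= 3 (the middle groups must be non-empty)",
         call. = FALSE)
  }
  if (M < s) stop("M must be at least s", call. = FALSE)
  if (strategy == "MAGA" && M %% s != 0) {
    stop("M must be divisible by s for strategy MAGA (got M = ", M,
         ", s = ", s, ")", call. = FALSE)
  }
  if (length(gene_range) != 2L || gene_range[1] >= gene_range[2]) {
    stop("gene_range must be an increasing interval", call. = FALSE)
  }
  if (max_generations < 1) stop("max_generations must be >= 1", call. = FALSE)
  for (nm in c("k1", "k2", "k3", "k4", "pc_fixed", "pm_fixed", "gauss_frac")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(M = as.integer(M), s = as.integer(s),
                 max_generations = as.integer(max_generations),
                 gene_range = as.numeric(gene_range), strategy = strategy,
                 k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 pc_fixed = pc_fixed, pm_fixed = pm_fixed,
                 blx_alpha = blx_alpha, gauss_frac = gauss_frac,
                 termination_epsilon = termination_epsilon,
                 seed = seed),
            class = "ga_config")
}

#' Initialize a random population
#'
#' Draws `M` individuals of `n_genes` genes, uniform over the gene range.
#'
#' @param config a [ga_config()] object.
#' @param n_genes genes per individual (default 10: nine coefficients plus
#'   the constant term).
#' @param seed optional seed; defaults to `config$seed`. Pass NULL (after
#'   seeding yourself) to draw from the current RNG state.
#' @return an object of class `"pbf_population"`: list with `genes`
#'   (M x n_genes matrix), `fitness` (NULL until evaluated) and
#'   `generation` (1).
#' @export
init_population <- function(config = ga_config(), n_genes = 10,
                            seed = config$seed) {
  if (!inherits(config, "ga_config")) stop("config must be a ga_config object",
                                           call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::runif(config$M * n_genes,
                           config$gene_range[1], config$gene_range[2]),
              nrow = config$M, ncol = n_genes)
  structure(list(genes = g, fitness = NULL, generation = 1L),
            class = "pbf_population")
}

#' Fitness of one individual
#'
#' The objective is the mean relative error of the individual's linear
#' predictions, `object = mean(|X w + b - F| / F)`, and the fitness is
#' `1 / (1 + object)`, in (0, 1]. A non-finite prediction yields fitness 0
#' with a warning.
#'
#' @param genes numeric vector: the feature coefficients followed by the
#'   constant term (length `ncol(X) + 1`).
#' @param X feature matrix of the training samples.
#' @param F observed PBF values (nonzero).
#' @return fitness in \[0, 1\].
#' @export
evaluate_fitness <- function(genes, X, F) {
  X <- as.matrix(X)
  if (length(genes) != ncol(X) + 1L) {
    stop("genes must have length ncol(X) + 1 (coefficients plus constant)",
         call. = FALSE)
  }
  p <- length(genes) - 1L
  pred <- as.vector(X %*% genes[seq_len(p)]) + genes[p + 1L]
  if (any(!is.finite(pred))) {
    warning("non-finite prediction; fitness set to 0")
    return(0)
  }
  1 / (1 + mean_relative_error(pred, F))
}

# Vectorized fitness of a whole population against a design matrix whose
# last column is the intercept carrier. Shares the objective definition
# with mean_relative_error / evaluate_fitness.
population_objective <- function(genes, B, F) {
  pred <- B %*% t(genes)
  obj <- colMeans(abs(pred - F) / F)
  obj[!is.finite(obj)] <- Inf
  obj
}

#' Roulette selection probabilities
#'
#' `p(k) = fit(k) / sum(fit)`. If every fitness is zero the probabilities
#' fall back to uniform, with a warning.
#'
#' @param fitness numeric vector of non-negative fitness values.
#' @return probability vector summing to 1.
#' @export
roulette_probabilities <- function(fitness) {
  if (any(!is.finite(fitness)) || any(fitness < 0)) {
    stop("fitness values must be finite and non-negative", call. = FALSE)
  }
  tot <- sum(fitness)
  if (tot == 0) {
    warning("all fitness values are zero; using uniform selection probabilities")
    return(rep(1 / length(fitness), length(fitness)))
  }
  fitness / tot
}

#' Grouped elitism/roulette/discard selection
#'
#' The modified selection operator: individuals are sorted by decreasing
#' fitness and split into `s` equal groups of M/s. The top group passes
#' unchanged to the next generation (and is exempt from crossover and
#' mutation there); the bottom group is discarded; the remaining
#' `(s-1)/s * M` slots are filled by roulette sampling, with replacement,
#' from the `(s-2)/s * M` middle individuals with probabilities
#' proportional to fitness renormalized over the middle.
#'
#' @param pop an evaluated `"pbf_population"`.
#' @param config a [ga_config()] object with `M` equal to the population
#'   size and divisible by `s`.
#' @return a `"pbf_population"` of the same size whose first `M/s` rows are
#'   the elites (attribute `"elite_rows"`), the rest the roulette draws.
#' @export
improved_select <- function(pop, config) {
  if (is.null(pop$fitness)) stop("population has no evaluated fitness", call. = FALSE)
  M <- nrow(pop$genes)
  s <- config$s
  if (M != config$M) stop("population size differs from config M", call. = FALSE)
  if (M %% s != 0) {
    stop("M must be divisible by s for the grouped selection operator",
         call. = FALSE)
  }
  ne <- M %/% s
  ord <- order(pop$fitness, decreasing = TRUE)
  genes <- pop$genes[ord, , drop = FALSE]
  fit <- pop$fitness[ord]
  elite <- genes[seq_len(ne), , drop = FALSE]
  mid_rows <- (ne + 1L):(M - ne)
  p_mid <- roulette_probabilities(fit[mid_rows])
  ndraw <- M - ne
  draw <- sample(mid_rows, ndraw, replace = TRUE, prob = p_mid)
  out_genes <- rbind(elite, genes[draw, , drop = FALSE])
  out_fit <- c(fit[seq_len(ne)], fit[draw])
  structure(list(genes = out_genes, fitness = out_fit,
                 generation = pop$generation),
            elite_rows = seq_len(ne),
            class = "pbf_population")
}

#' Single-elite retention selection
#'
#' The plain optimal-retention strategy: the fittest individual is copied
#' unchanged, the least fit is removed from the breeding pool, and the
#' remaining `M - 1` slots are filled by roulette over all but the worst.
#'
#' @param pop an evaluated `"pbf_population"`.
#' @return a `"pbf_population"` of the same size; row 1 is the retained
#'   best individual (attribute `"elite_rows"`).
#' @export
optimal_retention_select <- function(pop) {
  if (is.null(pop$fitness)) stop("population has no evaluated fitness", call. = FALSE)
  M <- nrow(pop$genes)
  ord <- order(pop$fitness, decreasing = TRUE)
  genes <- pop$genes[ord, , drop = FALSE]
  fit <- pop$fitness[ord]
  pool <- seq_len(M - 1L)  # all but the worst
  draw <- sample(pool, M - 1L, replace = TRUE,
                 prob = roulette_probabilities(fit[pool]))
  structure(list(genes = rbind(genes[1L, , drop = FALSE],
                               genes[draw, , drop = FALSE]),
                 fitness = c(fit[1L], fit[draw]),
                 generation = pop$generation),
            elite_rows = 1L,
            class = "pbf_population")
}

adaptive_pc <- function(f_parent, f_max, f_avg, config) {
  if (config$strategy == "GA") return(config$pc_fixed)
  if (f_max <= f_avg) return(config$k2)
  if (f_parent >= f_avg) config$k1 * (f_max - f_parent) / (f_max - f_avg)
  else config$k2
}

adaptive_pm <- function(f_ind, f_max, f_avg, config) {
  if (config$strategy == "GA") return(config$pm_fixed)
  if (f_max <= f_avg) return(config$k4)
  if (f_ind >= f_avg) config$k3 * (f_max - f_ind) / (f_max - f_avg)
  else config$k4
}

#' Adaptive blend crossover
#'
#' With probability `pc` — computed adaptively from the fitter parent's
#' fitness relative to the population maximum and mean, so above-average
#' parents are crossed less — the pair is recombined gene by gene with the
#' extended blend `child = lambda * p1 + (1 - lambda) * p2`,
#' `lambda ~ U(-blx_alpha, 1 + blx_alpha)` (BLX crossover; the extension
#' lets children sample slightly outside the parent interval). Children
#' are clipped to the gene range.
#'
#' @param parents 2 x n_genes matrix.
#' @param parent_fitness fitness of the two parents.
#' @param f_max,f_avg population maximum and mean fitness.
#' @param config a [ga_config()] object.
#' @param pc optional fixed crossover probability overriding the adaptive
#'   formula (used in tests and by the plain-GA strategy).
#' @return 2 x n_genes matrix of children.
#' @export
adaptive_crossover <- function(parents, parent_fitness, f_max, f_avg,
                               config = ga_config(), pc = NULL) {
  if (!is.matrix(parents) || nrow(parents) != 2L) {
    stop("parents must be a 2-row matrix", call. = FALSE)
  }
  if (is.null(pc)) pc <- adaptive_pc(max(parent_fitness), f_max, f_avg, config)
  if (stats::runif(1) >= pc) return(parents)
  ng <- ncol(parents)
  lam <- stats::runif(ng, -config$blx_alpha, 1 + config$blx_alpha)
  c1 <- lam * parents[1L, ] + (1 - lam) * parents[2L, ]
  c2 <- lam * parents[2L, ] + (1 - lam) * parents[1L, ]
  out <- rbind(c1, c2)
  out[] <- pmin(pmax(out, config$gene_range[1]), config$gene_range[2])
  rownames(out) <- NULL
  out
}

#' Adaptive mutation
#'
#' Each gene mutates independently with probability `pm`, computed
#' adaptively from the individual's fitness (fit individuals mutate less).
#' A mutated gene takes, with probability `gauss_frac`, a Gaussian step
#' whose standard deviation is the current spread of that gene over the
#' fittest group (local refinement), and otherwise a log-uniform step of
#' magnitude up to a tenth of the gene range (scale-free exploration).
#' Genes are clipped to the range.
#'
#' @param genes numeric gene vector.
#' @param fitness the individual's fitness.
#' @param f_max,f_avg population maximum and mean fitness.
#' @param config a [ga_config()] object.
#' @param step_sd per-gene Gaussian step scale; defaults to a tenth of the
#'   gene range for every gene.
#' @param pm optional fixed mutation probability overriding the adaptive
#'   formula.
#' @return mutated gene vector.
#' @export
adaptive_mutation <- function(genes, fitness, f_max, f_avg,
                              config = ga_config(), step_sd = NULL, pm = NULL) {
  ng <- length(genes)
  lo <- config$gene_range[1]
  hi <- config$gene_range[2]
  if (is.null(step_sd)) step_sd <- rep(0.1 * (hi - lo), ng)
  if (is.null(pm)) pm <- adaptive_pm(fitness, f_max, f_avg, config)
  mut <- which(stats::runif(ng) < pm)
  for (j in mut) {
    if (stats::runif(1) < config$gauss_frac) {
      genes[j] <- genes[j] + stats::rnorm(1, 0, max(step_sd[j], 1e-12))
    } else {
      step <- 0.1 * (hi - lo) * 2^(-16 * stats::runif(1))
      genes[j] <- genes[j] + sign(stats::runif(1) - 0.5) * step
    }
  }
  pmin(pmax(genes, lo), hi)
}

#' Run the genetic algorithm on a regression task
#'
#' Solves the coefficients of the linear model `F ~ X w + b` by minimizing
#' the mean relative error with the configured strategy. For numerical
#' conditioning the search runs, by default, on an orthonormalized basis of
#' the design matrix (QR decomposition scaled to unit root-mean-square
#' columns); the returned coefficients are back-transformed to the raw
#' feature scale. The run terminates when the best objective reaches
#' `termination_epsilon` or at `max_generations`.
#'
#' @param X feature matrix (one column per model feature, no intercept).
#' @param F observed target values, nonzero.
#' @param config a [ga_config()] object.
#' @param condition run the search on the orthonormalized basis
#'   (default TRUE). With FALSE the genes are the raw-scale coefficients
#'   themselves.
#' @param keep_populations record the gene matrix of every generation
#'   (default FALSE; intended for inspecting the selection dynamics).
#' @return a list with `omega` (feature coefficients), `b` (constant term),
#'   `fitness`, `object`, `genes` (internal-basis genes of the solution),
#'   `trace` (data frame: generation, best_fitness, mean_fitness),
#'   `terminated_by` (`"epsilon"` or `"max_generations"`),
#'   `generations` and, if requested, `populations`.
#' @export
evolve <- function(X, F, config = ga_config(), condition = TRUE,
                   keep_populations = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(F) != n) stop("X and F are inconsistent", call. = FALSE)
  if (any(F == 0)) stop("target contains zeros; relative error undefined",
                        call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  Xa <- cbind(X, 1)
  ng <- ncol(Xa)
  if (condition) {
    qrA <- qr(Xa)
    if (qrA$rank < ng) {
      stop("feature matrix is rank-deficient; remove collinear features",
           call. = FALSE)
    }
    B <- qr.Q(qrA) * sqrt(n)
    Rm <- qr.R(qrA)
  } else {
    B <- Xa
    Rm <- NULL
  }
  pop <- init_population(config, n_genes = ng, seed = NULL)
  M <- config$M
  ne <- max(1L, M %/% config$s)
  best_trace <- numeric(0)
  mean_trace <- numeric(0)
  populations <- if (keep_populations) list() else NULL
  terminated_by <- "max_generations"
  g <- 0L
  repeat {
    g <- g + 1L
    obj <- population_objective(pop$genes, B, F)
    fit <- 1 / (1 + obj)
    fit[!is.finite(fit)] <- 0
    pop$fitness <- fit
    if (keep_populations) {
      populations[[g]] <- list(genes = pop$genes, fitness = fit)
    }
    best_trace[g] <- max(fit)
    mean_trace[g] <- mean(fit)
    if (min(obj) <= config$termination_epsilon) {
      terminated_by <- "epsilon"
      break
    }
    if (g >= config$max_generations) break

    f_max <- max(fit)
    f_avg <- mean(fit)
    # step scale for the Gaussian mutation component: spread of each gene
    # over the fittest group
    top <- order(fit, decreasing = TRUE)[seq_len(ne)]
    step_sd <- apply(pop$genes[top, , drop = FALSE], 2, stats::sd)
    step_sd <- pmax(step_sd, 1e-12)

    if (config$strategy == "MAGA") {
      sel <- improved_select(pop, config)
      op_rows <- (ne + 1L):M
    } else {
      pr <- roulette_probabilities(fit)
      draw <- sample.int(M, M, replace = TRUE, prob = pr)
      sel <- structure(list(genes = pop$genes[draw, , drop = FALSE],
                            fitness = fit[draw],
                            generation = pop$generation),
                       class = "pbf_population")
      op_rows <- seq_len(M)
    }
    genes <- sel$genes
    qfit <- sel$fitness
    perm <- op_rows[sample.int(length(op_rows))]
    if (length(perm) >= 2L) {
      for (i in seq(1L, length(perm) - 1L, by = 2L)) {
        a <- perm[i]; b <- perm[i + 1L]
        ch <- adaptive_crossover(genes[c(a, b), , drop = FALSE],
                                 qfit[c(a, b)], f_max, f_avg, config)
        genes[a, ] <- ch[1L, ]
        genes[b, ] <- ch[2L, ]
      }
    }
    for (i in op_rows) {
      genes[i, ] <- adaptive_mutation(genes[i, ], qfit[i], f_max, f_avg,
                                      config, step_sd = step_sd)
    }
    pop$genes <- genes
    pop$fitness <- NULL
    pop$generation <- pop$generation + 1L
  }
  best_row <- which.max(pop$fitness)
  gamma <- pop$genes[best_row, ]
  full <- if (condition) backsolve(Rm, sqrt(n) * gamma) else gamma
  list(omega = full[seq_len(ng - 1L)],
       b = full[ng],
       genes = gamma,
       fitness = pop$fitness[best_row],
       object = 1 / pop$fitness[best_row] - 1,
       trace = data.frame(generation = seq_len(g),
                          best_fitness = best_trace,
                          mean_fitness = mean_trace),
       terminated_by = terminated_by,
       generations = g,
       populations = populations)
}
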