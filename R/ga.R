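#' MLP hyperparameter chromosome
#'
#' A chromosome is 4 real genes on \[0, 1) that decode, by scaled flooring,
#' to the hyperparameters of a two-hidden-layer perceptron: an activation
#' function (4 choices), a training solver (3 choices), and the two hidden
#' layer sizes (1..50 each) — a 30,000-point discrete search space.
#'
#' @param genes Numeric vector of length 4, each in \[0, 1).
#' @return An object of class `mlp_genotype`.
#' @export
mlp_genotype <- function(genes) {
  genes <- as.numeric(genes)
  if (length(genes) != 4L || anyNA(genes) || any(genes < 0) || any(genes >= 1)) {
    stop("genes must be 4 values in [0, 1)")
  }
  structure(list(genes = genes), class = "mlp_genotype")
}

#' @rdname mlp_genotype
#' @param genotype An `mlp_genotype`.
#' @return `decode_genotype()` returns a list with `activation_id` (0..3),
#'   `solver_id` (0..2), `h1`, `h2` (1..50), and the mapped `activation` /
#'   `solver` names.
#' @details Category mapping: activations 0..3 are identity, logistic, tanh,
#'   relu; solvers 0..2 are lbfgs, sgd, adam.
#' @export
decode_genotype <- function(genotype) {
  g <- genotype$genes
  if (anyNA(g) || any(g < 0) || any(g >= 1)) stop("genes out of [0, 1)")
  activation_id <- as.integer(floor(g[1L] * 4))
  solver_id <- as.integer(floor(g[2L] * 3))
  list(activation_id = activation_id,
       solver_id = solver_id,
       h1 = as.integer(floor(g[3L] * 50)) + 1L,
       h2 = as.integer(floor(g[4L] * 50)) + 1L,
       activation = activation_names()[activation_id + 1L],
       solver = solver_names()[solver_id + 1L])
}

activation_names <- function() c("identity", "logistic", "tanh", "relu")
solver_names <- function() c("lbfgs", "sgd", "adam")

genotype_key <- function(genotype) {
  d <- decode_genotype(genotype)
  paste(d$activation_id, d$solver_id, d$h1, d$h2, sep = "-")
}

#' @export
print.mlp_genotype <- function(x, ...) {
  d <- decode_genotype(x)
  cat(sprintf("mlp_genotype: activation=%s solver=%s hidden=(%d, %d) [genes %s]\n",
              d$activation, d$solver, d$h1, d$h2,
              paste(sprintf("%.3f", x$genes), collapse = ", ")))
  invisible(x)
}

#' Genetic algorithm configuration
#'
#' Defaults follow the standard design of this pipeline: tournament
#' selection with k = 4, single-point crossover at probability 1, per-gene
#' mutation at probability 0.001, population 50, 200 generations,
#' generational (non-elitist) replacement with a global-best archive.
#'
#' @param population_size Even integer >= 2. Default 50.
#' @param generations Number of generations. Default 200.
#' @param crossover_prob Crossover probability Pc in \[0, 1\]. Default 1.
#' @param mutation_prob Per-gene mutation probability Pm. Default 0.001.
#' @param tournament_k Tournament size, 1..population_size. Default 4.
#' @param seed Integer seed; a full GA run is bit-reproducible given it.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, generations = 200L,
                      crossover_prob = 1, mutation_prob = 0.001,
                      tournament_k = 4L, seed = 1L) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 2L || population_size %% 2L != 0L) {
    stop("population_size must be an even integer >= 2")
  }
  if (generations < 1L) stop("generations must be >= 1")
  if (crossover_prob < 0 || crossover_prob > 1) stop("crossover_prob must be in [0, 1]")
  if (mutation_prob < 0 || mutation_prob > 1) stop("mutation_prob must be in [0, 1]")
  tournament_k <- as.integer(tournament_k)
  if (tournament_k < 1L || tournament_k > population_size) {
    stop("tournament_k must be in 1..population_size")
  }
  structure(list(population_size = population_size, generations = generations,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 tournament_k = tournament_k, seed = as.integer(seed)),
            class = "ga_config")
}

#' Draw a random initial population
#'
#' Genes are i.i.d. uniform on \[0, 1). Uses the current RNG stream; callers
#' that need reproducibility seed it (as [run_ga()] does from `config$seed`).
#'
#' @param config A [ga_config()].
#' @return List of `population_size` [mlp_genotype()] objects.
#' @export
random_population <- function(config) {
  lapply(seq_len(config$population_size),
         function(i) mlp_genotype(stats::runif(4L)))
}

#' Tournament selection
#'
#' Samples `k` distinct contestants uniformly without replacement and
#' returns the one with the highest fitness; exact ties go to the lowest
#' population index.
#'
#' @param pop List of evaluated solutions, each a list with `genotype` and
#'   `fitness`.
#' @param k Tournament size.
#' @return The winning evaluated solution (with its population `index`).
#' @export
tournament_select <- function(pop, k) {
  n <- length(pop)
  if (n == 0L) stop("empty population")
  if (k < 1L || k > n) stop("tournament size k must be in 1..", n)
  idx <- sort(sample.int(n, k, replace = FALSE))
  fits <- vapply(pop[idx], function(s) s$fitness, numeric(1))
  winner <- idx[which.max(fits)]
  c(pop[[winner]], list(index = winner))
}

#' Single-point crossover of two chromosomes
#'
#' With probability `Pc`, draws a cut point c uniformly in \{1, 2, 3\} and
#' swaps the gene suffixes; otherwise the children are copies of the
#' parents. The per-locus gene multiset of the children always equals that
#' of the parents.
#'
#' @param p1,p2 Parent `mlp_genotype`s.
#' @param Pc Crossover probability.
#' @return List of two child `mlp_genotype`s.
#' @export
single_point_crossover <- function(p1, p2, Pc = 1) {
  g1 <- p1$genes
  g2 <- p2$genes
  if (Pc > 0 && stats::runif(1L) <= Pc) {
    cut <- sample.int(3L, 1L)
    tail_idx <- seq(cut + 1L, 4L)
    c1 <- c(g1[seq_len(cut)], g2[tail_idx])
    c2 <- c(g2[seq_len(cut)], g1[tail_idx])
    list(mlp_genotype(c1), mlp_genotype(c2))
  } else {
    list(mlp_genotype(g1), mlp_genotype(g2))
  }
}

#' Per-gene uniform-resample mutation
#'
#' Each gene is independently resampled uniform on \[0, 1) with probability
#' `Pm`.
#'
#' @param genotype An `mlp_genotype`.
#' @param Pm Per-gene mutation probability.
#' @return The (possibly) mutated `mlp_genotype`.
#' @export
mutate <- function(genotype, Pm = 0.001) {
  g <- genotype$genes
  hit <- stats::runif(4L) < Pm
  if (any(hit)) g[hit] <- stats::runif(sum(hit))
  mlp_genotype(g)
}

#' Run the genetic algorithm over MLP hyperparameter chromosomes
#'
#' Implements the generational GA this package is built around: evaluate a
#' random initial population; each generation, repeat `n/2` times (select
#' two parents by tournament, cross over with probability Pc, mutate with
#' per-gene probability Pm) to produce `n` children; children replace all
#' parents; the children are evaluated at the start of the next generation.
#' The best solution over all generations is kept in an archive outside the
#' (non-elitist) population and returned at the end. Fitness values are
#' cached by decoded genotype, so an MLP configuration is never evaluated
#' twice on the same data.
#'
#' @param config A [ga_config()].
#' @param fitness_fn Function `mlp_genotype -> fitness` (an accuracy
#'   percentage in \[0, 100\], higher is better). Must return a finite value.
#' @param verbose Print per-generation progress.
#' @return An object of class `ga_result`: list with `best` (list of
#'   `genotype`, `decoded`, `fitness`), `history` (data frame with one row
#'   per generation: `generation`, `best_fitness` — the archive, hence
#'   non-decreasing — and `mean_fitness` of that generation's population),
#'   `evaluations` (count of distinct decoded genotypes evaluated), and
#'   `config`.
#' @export
run_ga <- function(config, fitness_fn, verbose = FALSE) {
  stopifnot(inherits(config, "ga_config"), is.function(fitness_fn))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L

  eval_one <- function(genotype) {
    key <- genotype_key(genotype)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- fitness_fn(genotype)
    if (!is.numeric(fit) || length(fit) != 1L || !is.finite(fit)) {
      stop("non-finite fitness for genotype ", key)
    }
    n_eval <<- n_eval + 1L
    cache[[key]] <- fit
    fit
  }

  best <- NULL
  history <- vector("list", config$generations)

  with_seed(derive_seed(config$seed, "ga"), {
    pop_geno <- random_population(config)
    for (gen in seq_len(config$generations)) {
      pop <- lapply(pop_geno, function(g) list(genotype = g, fitness = eval_one(g)))
      gen_best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
      if (is.null(best) || gen_best$fitness > best$fitness) {
        best <- list(genotype = gen_best$genotype,
                     decoded = decode_genotype(gen_best$genotype),
                     fitness = gen_best$fitness)
      }
      history[[gen]] <- data.frame(
        generation = gen,
        best_fitness = best$fitness,
        mean_fitness = mean(vapply(pop, `[[`, numeric(1), "fitness")))
      if (verbose) {
        gamlp_log(sprintf("generation %d: best %.3f, mean %.3f", gen,
                          best$fitness, history[[gen]]$mean_fitness),
                  verbose = TRUE)
      }
      children <- vector("list", config$population_size)
      for (i in seq_len(config$population_size %/% 2L)) {
        pa <- tournament_select(pop, config$tournament_k)
        pb <- tournament_select(pop, config$tournament_k)
        kids <- single_point_crossover(pa$genotype, pb$genotype, config$crossover_prob)
        children[[2L * i - 1L]] <- mutate(kids[[1L]], config$mutation_prob)
        children[[2L * i]] <- mutate(kids[[2L]], config$mutation_prob)
      }
      pop_geno <- children
    }
    # evaluate the final children so the last breeding round can contribute
    for (g in pop_geno) {
      fit <- eval_one(g)
      if (is.null(best) || fit > best$fitness) {
        best <- list(genotype = g, decoded = decode_genotype(g), fitness = fit)
      }
    }
  })

  structure(list(best = best,
                 history = do.call(rbind, history),
                 evaluations = n_eval,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  d <- x$best$decoded
  cat(sprintf("ga_result: best fitness %.3f after %d generations (%d evaluations)\n",
              x$best$fitness, nrow(x$history), x$evaluations))
  cat(sprintf("  best MLP: activation=%s solver=%s hidden=(%d, %d)\n",
              d$activation, d$solver, d$h1, d$h2))
  invisible(x)
}
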