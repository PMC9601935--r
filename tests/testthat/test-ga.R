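test_that("chromosome decoding maps gene space to the hyperparameter grid", {
  lo <- decode_genotype(mlp_genotype(c(0, 0, 0, 0)))
  expect_equal(lo[c("activation_id", "solver_id", "h1", "h2")],
               list(activation_id = 0L, solver_id = 0L, h1 = 1L, h2 = 1L))
  hi <- decode_genotype(mlp_genotype(c(0.999, 0.999, 0.999, 0.999)))
  expect_equal(hi[c("activation_id", "solver_id", "h1", "h2")],
               list(activation_id = 3L, solver_id = 2L, h1 = 50L, h2 = 50L))
  mid <- decode_genotype(mlp_genotype(c(0.5, 0.5, 0.5, 0.5)))
  expect_equal(mid[c("activation_id", "solver_id", "h1", "h2")],
               list(activation_id = 2L, solver_id = 1L, h1 = 26L, h2 = 26L))
  expect_equal(mid$activation, "tanh")
  expect_equal(mid$solver, "sgd")
  expect_error(mlp_genotype(c(0, 0, 0, 1)), "\\[0, 1\\)")
  expect_error(mlp_genotype(c(-0.1, 0, 0, 0)), "\\[0, 1\\)")
})

test_that("random populations have the right size, bounds, and reproducibility", {
  cfg <- ga_config(population_size = 50, seed = 1)
  p1 <- withr::with_seed(1, random_population(cfg))
  expect_length(p1, 50L)
  genes <- unlist(lapply(p1, `[[`, "genes"))
  expect_true(all(genes >= 0 & genes < 1))
  p2 <- withr::with_seed(1, random_population(cfg))
  expect_identical(p1, p2)
  cfg2 <- ga_config(population_size = 2, tournament_k = 2)
  expect_length(withr::with_seed(2, random_population(cfg2)), 2L)
})

test_that("ga_config validates its invariants", {
  expect_error(ga_config(population_size = 3), "even")
  expect_error(ga_config(population_size = 0), "even")
  expect_error(ga_config(crossover_prob = 1.2), "\\[0, 1\\]")
  expect_error(ga_config(tournament_k = 9, population_size = 8), "tournament_k")
})

test_that("tournament selection returns the fittest contestant with index tie-breaks", {
  mk <- function(fits) lapply(seq_along(fits), function(i) {
    list(genotype = mlp_genotype(rep(i / 100, 4)), fitness = fits[i])
  })
  pop <- mk(c(40, 90, 10, 70))
  # exhaustive tournament -> global best
  win <- withr::with_seed(1, tournament_select(pop, k = 4))
  expect_equal(win$fitness, 90)
  expect_equal(win$index, 2L)
  # two contestants {40, 90}
  win2 <- withr::with_seed(3, tournament_select(mk(c(40, 90)), k = 2))
  expect_equal(win2$fitness, 90)
  # all equal -> lowest sampled population index, reproducibly
  tied <- mk(c(5, 5, 5, 5, 5))
  w1 <- withr::with_seed(7, tournament_select(tied, k = 3))
  w2 <- withr::with_seed(7, tournament_select(tied, k = 3))
  expect_identical(w1$index, w2$index)
  expect_equal(withr::with_seed(7, sort(sample.int(5, 3)))[1], w1$index)
  expect_error(tournament_select(list(), 1), "empty population")
  expect_error(tournament_select(tied, 6), "1..5")
})

test_that("single-point crossover swaps suffixes and conserves the per-locus gene multiset", {
  p1 <- mlp_genotype(c(0.1, 0.2, 0.3, 0.4))
  p2 <- mlp_genotype(c(0.5, 0.6, 0.7, 0.8))
  # every outcome must be one of the three exact suffix exchanges, and all
  # three cut points must occur across seeds
  expected <- lapply(1:3, function(cut) {
    idx <- seq(cut + 1, 4)
    list(replace(p1$genes, idx, p2$genes[idx]),
         replace(p2$genes, idx, p1$genes[idx]))
  })
  cuts_seen <- integer(0)
  for (s in 1:20) {
    kids <- withr::with_seed(s, single_point_crossover(p1, p2, Pc = 1))
    cut <- which(vapply(expected, function(e) {
      identical(e[[1]], kids[[1]]$genes) && identical(e[[2]], kids[[2]]$genes)
    }, logical(1)))
    expect_length(cut, 1L)
    cuts_seen <- union(cuts_seen, cut)
  }
  expect_setequal(cuts_seen, 1:3)
  # Pc = 0: children are copies
  copies <- withr::with_seed(1, single_point_crossover(p1, p2, Pc = 0))
  expect_equal(copies[[1]]$genes, p1$genes)
  expect_equal(copies[[2]]$genes, p2$genes)
  # conservation across many random draws
  withr::with_seed(9, {
    for (i in 1:100) {
      g1 <- mlp_genotype(runif(4)); g2 <- mlp_genotype(runif(4))
      ch <- single_point_crossover(g1, g2, Pc = 1)
      for (locus in 1:4) {
        expect_setequal(c(ch[[1]]$genes[locus], ch[[2]]$genes[locus]),
                        c(g1$genes[locus], g2$genes[locus]))
      }
    }
  })
})

test_that("mutation is a per-gene Bernoulli uniform resample", {
  g <- mlp_genotype(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(withr::with_seed(1, mutate(g, Pm = 0))$genes, g$genes)
  m1 <- withr::with_seed(2, mutate(g, Pm = 1))
  m2 <- withr::with_seed(2, mutate(g, Pm = 1))
  expect_identical(m1$genes, m2$genes)
  expect_true(all(m1$genes != g$genes))
})

test_that("run_ga follows the generational loop with caching and a monotone archive", {
  calls <- new.env(); calls$n <- 0L
  fit_fn <- function(g) { calls$n <- calls$n + 1L; decode_genotype(g)$h1 }
  res <- run_ga(ga_config(population_size = 4, generations = 1, seed = 3), fit_fn)
  # 4 parents + 4 children at most; caching can only reduce the count
  expect_lte(calls$n, 8L)
  expect_equal(res$evaluations, calls$n)
  expect_equal(nrow(res$history), 1L)

  res2 <- run_ga(ga_config(population_size = 10, generations = 15,
                           mutation_prob = 0.05, seed = 5),
                 function(g) sum(g$genes))
  expect_true(all(diff(res2$history$best_fitness) >= 0))
  expect_gte(res2$best$fitness, max(res2$history$best_fitness))

  # with Pm = 0 and Pc = 0 the gene pool is closed: no new genotypes appear
  calls$n <- 0L
  res3 <- run_ga(ga_config(population_size = 10, generations = 20,
                           crossover_prob = 0, mutation_prob = 0, seed = 7),
                 fit_fn)
  expect_lte(res3$evaluations, 10L)
})

test_that("run_ga is bit-reproducible given the seed and rejects non-finite fitness", {
  fit <- function(g) 100 * g$genes[1]
  r1 <- run_ga(ga_config(population_size = 8, generations = 10, seed = 42), fit)
  r2 <- run_ga(ga_config(population_size = 8, generations = 10, seed = 42), fit)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$history, r2$history)
  expect_error(run_ga(ga_config(population_size = 4, generations = 1, seed = 1),
                      function(g) NaN),
               "non-finite fitness")
})
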