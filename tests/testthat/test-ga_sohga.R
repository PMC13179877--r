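test_that("configuration validates ranges and loads from YAML", {
  expect_error(ga_config(crossover_rate = 1.2))
  expect_error(ga_config(elitist_num = 80, population_size = 80))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(population_size = 30, num_generations = 5,
                        crossover_rate = 0.9, mutation_rate = 0.8,
                        rng_seed = 9), path)
  cfg <- read_ga_config(path)
  expect_equal(cfg$population_size, 30L)
  expect_equal(cfg$rng_seed, 9L)
  yaml::write_yaml(list(population_size = 30, bogus = 1), path)
  expect_error(read_ga_config(path), "unknown")
})

test_that("tournament selection prefers lower fitness with closed-form rates", {
  mk <- function(key, fitness, nep = 5L)
    pkmoo:::new_eval_record(genome_from_key(key), NULL, NULL, NULL,
                            fitness, nep, fitness,
                            list(converged = TRUE, covariance_ok = TRUE,
                                 correlation_ok = TRUE, condition_ok = TRUE))
  pop2 <- list(mk("00", 1060), mk("11", 1200))
  set.seed(131)
  for (i in 1:50) expect_equal(tournament_select(pop2)$fitness, 1060)
  # identical records: the record itself is returned
  same <- list(mk("01", 500), mk("01", 500))
  expect_equal(tournament_select(same)$key, "01")
  # ranked population of 5, distinct pair per tournament:
  # P(select rank i) = 2 (N - i) / (N (N - 1)); the worst is never selected
  N <- 5L
  pop <- lapply(1:N, function(i) mk(paste(rev(as.integer(intToBits(i)[1:3])),
                                          collapse = ""), 1000 + 10 * i))
  set.seed(141)
  draws <- replicate(10000, tournament_select(pop)$fitness)
  freq <- as.numeric(table(factor(draws, levels = 1000 + 10 * (1:N)))) / 10000
  p_theory <- 2 * (N - (1:N)) / (N * (N - 1))
  expect_true(all(diff(freq) < 0))
  expect_true(all(abs(freq - p_theory) <
                    4 * sqrt(p_theory * (1 - p_theory) / 10000) + 1e-9))
})

test_that("single-point crossover swaps tails and conserves loci", {
  a <- c(1L, 1L, 1L, 0L, 0L, 0L)
  b <- c(0L, 0L, 0L, 1L, 1L, 1L)
  set.seed(151)
  kids <- crossover(a, b, rate = 0)
  expect_identical(kids, list(a, b))
  valid <- lapply(1:5, function(cut)
    sort(c(genome_key(c(a[1:cut], b[(cut + 1):6])),
           genome_key(c(b[1:cut], a[(cut + 1):6])))))
  for (i in 1:30) {
    kids <- crossover(a, b, rate = 1)
    keys <- sort(vapply(kids, genome_key, character(1)))
    expect_true(any(vapply(valid, identical, logical(1), keys)))
    # locus-wise bit conservation
    expect_equal(kids[[1]] + kids[[2]], a + b)
  }
})

test_that("mutation flips exactly one uniformly chosen bit", {
  g <- rep(0L, 12)
  set.seed(161)
  expect_identical(mutate(g, rate = 0), g)
  flips <- integer(12)
  for (i in 1:12000) {
    m <- mutate(g, rate = 1)
    d <- which(m != g)
    expect_length(d, 1L)
    flips[d] <- flips[d] + 1L
  }
  p <- 1 / 12
  expect_true(all(abs(flips / 12000 - p) < 3 * sqrt(p * (1 - p) / 12000)))
})

test_that("downhill reaches the greedy steepest-descent fixed point", {
  space <- binary_effect_space(10L, effect_limit = Inf)
  # independent greedy oracle over the frozen lookup fitness
  greedy_oracle <- function(fitness_of, g) {
    repeat {
      nb <- one_bit_neighbors(g)
      f <- vapply(nb, fitness_of, numeric(1))
      if (min(f) < fitness_of(g)) { g <- nb[[which.min(f)]]; next }
      nb2 <- two_bit_neighbors(g)
      f2 <- vapply(nb2, fitness_of, numeric(1))
      if (min(f2) < fitness_of(g)) { g <- nb2[[which.min(f2)]]; next }
      return(g)
    }
  }
  set.seed(171)
  seeds <- replicate(50, random_genome(10L), simplify = FALSE)
  ev <- make_lookup_evaluator(space, seed = 172L)
  fitness_of <- function(g) ev(g)$fitness
  for (g in seeds) {
    res <- downhill(ev(g), ev, two_bit_enabled = TRUE)
    expect_equal(res$fitness, fitness_of(greedy_oracle(fitness_of, g)))
    expect_lte(res$fitness, fitness_of(g))
    # local optimality of the endpoint in both neighbourhoods
    nb_fit <- vapply(c(one_bit_neighbors(res$genome),
                       two_bit_neighbors(res$genome)), fitness_of, numeric(1))
    expect_true(all(nb_fit >= res$fitness))
  }
})

test_that("a strict local minimum is returned unchanged after n evaluations", {
  space <- binary_effect_space(6L, effect_limit = Inf)
  # fitness = Hamming weight: the all-zero genome is the global minimum
  ev <- table_evaluator(space, function(g, ph) 100 + 10 * sum(g))
  seed <- ev(rep(0L, 6))
  res <- downhill(seed, ev, two_bit_enabled = FALSE)
  expect_equal(res$key, seed$key)
  expect_equal(attr(res, "n_evals"), 6L)
})

test_that("the hybrid search finds the enumerated optimum and is deterministic", {
  space <- binary_effect_space(10L, effect_limit = Inf)
  ev0 <- make_lookup_evaluator(space, seed = 181L)
  truth <- exhaustive_search(space, ev0)
  best_true <- min(vapply(truth, `[[`, numeric(1), "fitness"))
  cfg <- ga_config(population_size = 30L, num_generations = 8L,
                   downhill_period = 4L, rng_seed = 5L)
  ev1 <- make_lookup_evaluator(space, seed = 181L)
  run1 <- sohga_search(space, ev1, cfg)
  expect_equal(run1$best$fitness, best_true)
  ev2 <- make_lookup_evaluator(space, seed = 181L)
  run2 <- sohga_search(space, ev2, cfg)
  expect_identical(run1$history, run2$history)
  expect_identical(run1$best$key, run2$best$key)
  # elitism: per-generation population minimum never increases
  gen_min <- tapply(run1$history$fitness, run1$history$generation, min)
  expect_true(all(diff(gen_min) <= 1e-12))
  # worker-count contract: num_parallel does not change the trajectory
  ev3 <- make_lookup_evaluator(space, seed = 181L)
  run3 <- sohga_search(space, ev3, ga_config(population_size = 30L,
                                             num_generations = 8L,
                                             downhill_period = 4L,
                                             rng_seed = 5L,
                                             num_parallel = 4L))
  expect_identical(run1$history, run3$history)
})

test_that("niche heads stay mutually distant and selection alone shrinks diversity", {
  space <- binary_effect_space(8L, effect_limit = Inf)
  ev <- make_lookup_evaluator(space, seed = 191L)
  set.seed(201)
  pop <- lapply(replicate(20, random_genome(8L), simplify = FALSE), ev)
  heads <- pkmoo:::niche_heads(pop, num_niches = 3L, niche_radius = 2L)
  if (length(heads) > 1L)
    for (i in 1:(length(heads) - 1)) for (j in (i + 1):length(heads))
      expect_gt(sum(heads[[i]]$genome != heads[[j]]$genome), 2L)
  # with no crossover, mutation, or downhill, genomes can only be copied
  cfg <- ga_config(population_size = 20L, num_generations = 6L,
                   crossover_rate = 0, mutation_rate = 0,
                   downhill_period = 100L, rng_seed = 7L)
  ev2 <- make_lookup_evaluator(space, seed = 191L)
  run <- sohga_search(space, ev2, cfg)
  uniq <- tapply(run$history$genome, run$history$generation,
                 function(k) length(unique(k)))
  expect_true(all(diff(uniq) <= 0))
})

test_that("downhill evaluation budget matches the neighbourhood sizes", {
  space <- binary_effect_space(8L, effect_limit = Inf)
  ev <- make_lookup_evaluator(space, seed = 211L)
  set.seed(221)
  g <- random_genome(8L)
  res <- downhill(ev(g), ev, two_bit_enabled = TRUE)
  n <- 8L
  n_evals <- attr(res, "n_evals")
  # at most (moves + stalls) one-bit sweeps plus stall two-bit sweeps; the
  # move count is bounded by the number of evaluations divided by n
  iters <- ceiling(n_evals / n)
  expect_lte(n_evals, iters * n + iters * n * (n - 1) / 2)
})
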