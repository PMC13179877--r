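ov <- function(ofv, nep) list(ofv = ofv, nep = nep)

test_that("domination requires no-worse on both objectives and better on one", {
  expect_true(dominates(ov(8034.5, 5), ov(8040.0, 6)))
  expect_false(dominates(ov(8034.5, 5), ov(8034.5, 5)))
  # trade-off: published front endpoints coexist
  expect_false(dominates(ov(8024.6, 23), ov(9813.4, 5)))
  expect_false(dominates(ov(9813.4, 5), ov(8024.6, 23)))
  expect_true(dominates(ov(100, 5), ov(100, 6)))
})

test_that("non-dominated sorting peels fronts in domination order", {
  # mutually non-dominated staircase -> one front
  obj <- cbind(ofv = c(10, 8, 6), nep = c(1, 2, 3))
  expect_length(non_dominated_sort(obj), 1L)
  # strict chain -> singleton fronts in order
  chain <- cbind(ofv = c(1, 2, 3), nep = c(1, 2, 3))
  expect_equal(non_dominated_sort(chain), list(1L, 2L, 3L))
})

test_that("sorting matches the brute-force pairwise oracle on random vectors", {
  set.seed(231)
  for (rep in 1:5) {
    obj <- cbind(ofv = round(runif(200, 1000, 1100), 1),
                 nep = sample(3:25, 200, replace = TRUE))
    fronts <- non_dominated_sort(obj)
    rank <- integer(200)
    for (k in seq_along(fronts)) rank[fronts[[k]]] <- k
    expect_equal(rank, brute_force_fronts(obj))
  }
})

test_that("crowding distance follows the normalized neighbour-gap formula", {
  # two-member front: all boundary
  expect_equal(crowding_distance(cbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  # worked three-point case: middle = (2-0)/2 + (2-0)/2 = 2
  front <- cbind(ofv = c(0, 1, 2), nep = c(2, 1, 0))
  expect_equal(crowding_distance(front), c(Inf, 2, Inf))
  # permutation invariance
  perm <- c(2, 3, 1)
  expect_equal(crowding_distance(front[perm, ]),
               crowding_distance(front)[perm])
  # scale invariance: multiplying one objective by a positive constant
  set.seed(241)
  nep <- sample(1:40, 12)
  stair <- cbind(ofv = sort(runif(12, 100, 200), decreasing = TRUE),
                 nep = sort(nep))
  expect_equal(crowding_distance(stair),
               crowding_distance(cbind(stair[, 1] * 37.5, stair[, 2])))
})

test_that("environmental selection truncates by crowding with elitism", {
  mk <- function(key, ofv, nep)
    pkmoo:::new_eval_record(genome_from_key(key), NULL, NULL, NULL, ofv,
                            as.integer(nep), ofv,
                            list(converged = TRUE, covariance_ok = TRUE,
                                 correlation_ok = TRUE, condition_ok = TRUE))
  # one front larger than capacity: keep the largest-crowding members
  keys <- sprintf("%04d", 0:7)
  pool <- lapply(1:8, function(i)
    mk(keys[i], 100 - i, i))
  kept <- environmental_selection(pool, 5L)
  cd <- crowding_distance(pool)
  expect_setequal(vapply(kept, `[[`, character(1), "key"),
                  vapply(pool[order(-cd)][1:5], `[[`, character(1), "key"))
  # all-identical objectives: any capacity-many kept, deterministic under
  # the tie-break and invariant to pool order
  pool2 <- lapply(1:6, function(i) mk(sprintf("%03d", i), 50, 4))
  kept2 <- sort(vapply(environmental_selection(pool2, 3L), `[[`,
                       character(1), "key"))
  set.seed(991)
  kept2b <- sort(vapply(environmental_selection(pool2[sample(6)], 3L), `[[`,
                        character(1), "key"))
  expect_equal(kept2, kept2b)
  expect_length(kept2, 3L)
  # random pools: agreement with an independently coded reference selector
  set.seed(251)
  for (rep in 1:10) {
    pool3 <- lapply(1:30, function(i)
      mk(paste(random_genome(10L), collapse = ""),
         round(runif(1, 100, 120), 1), sample(2:12, 1)))
    keep_n <- 12L
    kept3 <- environmental_selection(pool3, keep_n)
    ref <- local({
      obj <- cbind(vapply(pool3, `[[`, numeric(1), "ofv"),
                   vapply(pool3, function(r) as.numeric(r$nep), numeric(1)))
      rank <- brute_force_fronts(obj)
      chosen <- integer(0)
      for (r in sort(unique(rank))) {
        fr <- which(rank == r)
        if (length(chosen) + length(fr) <= keep_n) {
          chosen <- c(chosen, fr)
        } else {
          cd <- crowding_distance(obj[fr, , drop = FALSE])
          key <- vapply(pool3[fr], `[[`, character(1), "key")
          fr <- fr[order(-cd, obj[fr, 2], key)]
          chosen <- c(chosen, fr[seq_len(keep_n - length(chosen))])
          break
        }
      }
      sort(vapply(pool3[chosen], `[[`, character(1), "key"))
    })
    expect_equal(sort(vapply(kept3, `[[`, character(1), "key")), ref)
  }
})

test_that("rank-1 members always survive selection when they fit", {
  set.seed(261)
  mk <- function(i, ofv, nep)
    pkmoo:::new_eval_record(as.integer(intToBits(i)[8:1]), NULL, NULL, NULL,
                            ofv, as.integer(nep), ofv,
                            list(converged = TRUE, covariance_ok = TRUE,
                                 correlation_ok = TRUE, condition_ok = TRUE))
  pool <- lapply(1:40, function(i)
    mk(i, round(runif(1, 100, 150), 1), sample(2:15, 1)))
  front1 <- pareto_front(pool)
  kept <- environmental_selection(pool, 20L)
  expect_true(all(vapply(front1, `[[`, character(1), "key") %in%
                    vapply(kept, `[[`, character(1), "key")))
})

test_that("the archive forms a strict Pareto staircase", {
  space <- binary_effect_space(10L, effect_limit = Inf)
  ev <- make_lookup_evaluator(space, seed = 271L)
  recs <- exhaustive_search(space, ev)
  front <- pareto_front(recs)
  nep <- vapply(front, function(r) as.numeric(r$nep), numeric(1))
  ofv <- vapply(front, `[[`, numeric(1), "ofv")
  expect_true(all(diff(nep) > 0))
  expect_true(all(diff(ofv) < 0))
})

test_that("multi-objective downhill only improves the archive", {
  space <- binary_effect_space(10L, effect_limit = Inf)
  ev <- make_lookup_evaluator(space, seed = 281L)
  set.seed(291)
  start <- lapply(replicate(8, random_genome(10L), simplify = FALSE), ev)
  arch0 <- pareto_front(start)
  ref <- c(max(vapply(start, `[[`, numeric(1), "ofv")) + 1,
           max(vapply(start, function(r) as.numeric(r$nep), numeric(1))) + 1)
  hv0 <- hypervolume2d(arch0, ref)
  arch1 <- moo_downhill(arch0, ev, two_bit_enabled = TRUE)
  expect_gte(hypervolume2d(arch1, ref), hv0)
  # nothing in the old archive dominates the new one
  for (new in arch1)
    expect_false(any(vapply(arch0, function(old) dominates(old, new),
                            logical(1))))
  # a second pass is a no-op: the archive is locally Pareto-optimal
  arch2 <- moo_downhill(arch1, ev, two_bit_enabled = TRUE)
  expect_setequal(vapply(arch2, `[[`, character(1), "key"),
                  vapply(arch1, `[[`, character(1), "key"))
})

test_that("the multi-objective search recovers the exact front and is deterministic", {
  space <- binary_effect_space(10L, effect_limit = Inf)
  truth <- pareto_front(exhaustive_search(space,
                                          make_lookup_evaluator(space, 301L)))
  truth_keys <- vapply(truth, `[[`, character(1), "key")
  cfg <- ga_config(population_size = 60L, num_generations = 15L,
                   downhill_period = 5L, elitist_num = 0L, rng_seed = 3L)
  ev1 <- make_lookup_evaluator(space, 301L)
  run1 <- nsga2_search(space, ev1, cfg)
  expect_setequal(vapply(run1$archive, `[[`, character(1), "key"), truth_keys)
  ev2 <- make_lookup_evaluator(space, 301L)
  run2 <- nsga2_search(space, ev2, cfg)
  expect_identical(run1$history, run2$history)
  expect_identical(vapply(run1$archive, `[[`, character(1), "key"),
                   vapply(run2$archive, `[[`, character(1), "key"))
})

test_that("with equal NEP everywhere the search collapses to the OFV optimum", {
  # every option is parameter-neutral, so NEP is constant across the space
  space_flat <- search_space(lapply(1:8, function(i)
    token_set(paste0("s", i), list(token_option("a"), token_option("b")))))
  truth <- exhaustive_search(space_flat,
                             make_lookup_evaluator(space_flat, 351L))
  best_ofv <- min(vapply(truth, `[[`, numeric(1), "ofv"))
  ev <- make_lookup_evaluator(space_flat, 351L)
  run <- suppressMessages(
    nsga2_search(space_flat, ev, ga_config(population_size = 40L,
                                           num_generations = 12L,
                                           downhill_period = 4L,
                                           rng_seed = 11L)))
  expect_length(run$archive, 1L)
  expect_equal(run$archive[[1]]$ofv, best_ofv)
  # and it coincides with the single-objective optimum: with constant NEP
  # the penalty is a constant shift
  evs <- make_lookup_evaluator(space_flat, 351L)
  runs <- sohga_search(space_flat, evs,
                       ga_config(population_size = 40L,
                                 num_generations = 12L,
                                 downhill_period = 4L, rng_seed = 11L))
  expect_equal(runs$best$ofv, best_ofv)
})

test_that("every evaluated model satisfies the effect limit", {
  space <- binary_effect_space(8L, effect_limit = 3L)
  ev <- make_lookup_evaluator(space, seed = 321L)
  run <- suppressMessages(
    nsga2_search(space, ev, ga_config(population_size = 20L,
                                      num_generations = 6L,
                                      downhill_period = 3L,
                                      rng_seed = 13L)))
  # the limit holds for every evaluation, including downhill neighbours
  eff <- vapply(evaluated_records(ev), function(r)
    decode(space, r$genome)$total_effects, integer(1))
  expect_true(all(eff <= 3L))
})
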