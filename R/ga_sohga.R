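#' Genetic-algorithm configuration
#'
#' Defaults follow the published hyperparameters of the single-objective
#' hybrid search: population 80, 20 generations, crossover and mutation
#' rates 0.95, 4 elites, 2 niches of radius 2 bits, downhill every 5
#' generations.  `num_parallel` is a worker-count contract for model
#' evaluation; results are independent of its value.
#'
#' @param population_size models per generation.
#' @param num_generations generations to run.
#' @param crossover_rate probability a parent pair undergoes single-point
#'   crossover.
#' @param mutation_rate probability a new candidate has one uniformly chosen
#'   bit flipped.
#' @param elitist_num best models carried over unchanged.
#' @param num_niches,niche_radius niche count and minimum Hamming distance
#'   (bits) between niche heads.
#' @param downhill_period generations between local downhill searches.
#' @param two_bit_enabled run the two-bit pass when the one-bit search
#'   stalls.
#' @param num_parallel worker-count contract (results are identical for any
#'   value).
#' @param rng_seed seed of the single RNG used by the whole search.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 80L, num_generations = 20L,
                      crossover_rate = 0.95, mutation_rate = 0.95,
                      elitist_num = 4L, num_niches = 2L, niche_radius = 2L,
                      downhill_period = 5L, two_bit_enabled = TRUE,
                      num_parallel = 1L, rng_seed = 1L) {
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitist_num < population_size, downhill_period >= 1,
            population_size >= 2, num_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 num_generations = as.integer(num_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitist_num = as.integer(elitist_num),
                 num_niches = as.integer(num_niches),
                 niche_radius = as.integer(niche_radius),
                 downhill_period = as.integer(downhill_period),
                 two_bit_enabled = isTRUE(two_bit_enabled),
                 num_parallel = as.integer(num_parallel),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Read an algorithm configuration file
#'
#' YAML/JSON file whose keys mirror the published hyperparameter names
#' (`population_size`, `num_generations`, `crossover_rate`,
#' `mutation_rate`, `elitist_num`, `num_niches`, `niche_radius`,
#' `downhill_period`, `num_parallel`, plus `two_bit_enabled` and
#' `rng_seed`).  Unknown keys are rejected.
#'
#' @param path file path.
#' @return a [ga_config()].
#' @export
read_ga_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(ga_config))
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  do.call(ga_config, doc)
}

hamming <- function(a, b) sum(a != b)

# Total order used for every tie-break: fitness, then NEP, then bit string.
record_before <- function(a, b) {
  if (a$fitness != b$fitness) return(a$fitness < b$fitness)
  an <- if (is.na(a$nep)) Inf else a$nep
  bn <- if (is.na(b$nep)) Inf else b$nep
  if (an != bn) return(an < bn)
  a$key < b$key
}

order_records <- function(records) {
  fit <- vapply(records, `[[`, numeric(1), "fitness")
  nep <- vapply(records, function(r) if (is.na(r$nep)) Inf else
    as.numeric(r$nep), numeric(1))
  key <- vapply(records, `[[`, character(1), "key")
  order(fit, nep, key)
}

#' Binary tournament selection on composite fitness
#'
#' Draws a pair of distinct population members uniformly (with replacement
#' across tournaments) and returns the one with lower fitness; ties broken
#' by lower NEP then lexicographic bit string.
#'
#' @param population list of `eval_record`s.
#' @return the selected `eval_record`.
#' @export
tournament_select <- function(population) {
  if (length(population) == 1L) return(population[[1L]])
  i <- sample.int(length(population), 2L)
  a <- population[[i[1]]]; b <- population[[i[2]]]
  if (record_before(a, b)) a else b
}

#' Single-point crossover
#'
#' With probability `rate` a single cut point is drawn uniformly in
#' `[1, n-1]` and the tails are swapped; otherwise the children are copies
#' of the parents.
#'
#' @param parent_a,parent_b genomes of equal length.
#' @param rate crossover probability.
#' @return list of two child genomes.
#' @export
crossover <- function(parent_a, parent_b, rate = 0.95) {
  stopifnot(length(parent_a) == length(parent_b))
  n <- length(parent_a)
  if (n >= 2L && stats::runif(1) < rate) {
    cut <- sample.int(n - 1L, 1L)
    list(c(parent_a[1:cut], parent_b[(cut + 1L):n]),
         c(parent_b[1:cut], parent_a[(cut + 1L):n]))
  } else {
    list(parent_a, parent_b)
  }
}

#' One-bit mutation
#'
#' With probability `rate` the candidate is mutated: exactly one uniformly
#' chosen bit is flipped.  The published rate (0.95) is per candidate, not
#' per bit.
#'
#' @param genome a genome.
#' @param rate mutation probability.
#' @return the (possibly) mutated genome.
#' @export
mutate <- function(genome, rate = 0.95) {
  if (stats::runif(1) < rate) {
    i <- sample.int(length(genome), 1L)
    genome[i] <- 1L - genome[i]
  }
  genome
}

#' Steepest-descent bit-flip downhill search
#'
#' From an evaluated seed, repeatedly evaluates all `n` one-bit neighbours
#' and moves to the single best strictly improving one.  When the one-bit
#' search stalls and `two_bit_enabled`, all `n(n-1)/2` two-bit neighbours
#' are evaluated once; if one improves, the search moves there and resumes
#' the one-bit loop, otherwise it terminates.  The returned record is a
#' one-bit (and, when enabled, two-bit) local minimum of the composite
#' fitness, never worse than the seed.
#'
#' @param seed_record an evaluated `eval_record`.
#' @param evaluator evaluator closure (see [pk_evaluator()]).
#' @param two_bit_enabled logical.
#' @return the final `eval_record`, with attribute `n_evals` (evaluator
#'   calls spent).
#' @export
downhill <- function(seed_record, evaluator, two_bit_enabled = TRUE) {
  current <- seed_record
  n_evals <- 0L
  space <- attr(evaluator, "space")
  admissible <- function(genomes) {
    if (is.null(space) || !is.finite(space$effect_limit)) return(genomes)
    # models exceeding the effect limit are discarded before running
    genomes[vapply(genomes, function(g)
      decode(space, g)$total_effects <= space$effect_limit, logical(1))]
  }
  repeat {
    cand <- lapply(admissible(one_bit_neighbors(current$genome)), evaluator)
    n_evals <- n_evals + length(cand)
    best <- if (length(cand)) cand[[order_records(cand)[1]]] else NULL
    if (!is.null(best) && best$fitness < current$fitness) {
      current <- best
      next
    }
    if (two_bit_enabled) {
      cand2 <- lapply(admissible(two_bit_neighbors(current$genome)),
                      evaluator)
      n_evals <- n_evals + length(cand2)
      if (length(cand2)) {
        best2 <- cand2[[order_records(cand2)[1]]]
        if (best2$fitness < current$fitness) {
          current <- best2
          next
        }
      }
    }
    break
  }
  attr(current, "n_evals") <- n_evals
  current
}

# Greedy niche assignment: scan records by ascending fitness; a record
# founds a new niche if its Hamming distance to every existing head exceeds
# the niche radius, until num_niches heads exist.
niche_heads <- function(population, num_niches, niche_radius) {
  ord <- order_records(population)
  heads <- list()
  for (i in ord) {
    r <- population[[i]]
    if (length(heads) == 0L ||
        all(vapply(heads, function(h) hamming(h$genome, r$genome),
                   numeric(1)) > niche_radius))
      heads <- c(heads, list(r))
    if (length(heads) >= num_niches) break
  }
  heads
}

# Elitist slots: round-robin across niche heads, then by global fitness.
pick_elites <- function(population, config) {
  heads <- niche_heads(population, config$num_niches, config$niche_radius)
  elites <- list()
  keys <- character(0)
  for (h in heads) {
    if (length(elites) >= config$elitist_num) break
    if (!h$key %in% keys) { elites <- c(elites, list(h)); keys <- c(keys, h$key) }
  }
  for (i in order_records(population)) {
    if (length(elites) >= config$elitist_num) break
    r <- population[[i]]
    if (!r$key %in% keys) { elites <- c(elites, list(r)); keys <- c(keys, r$key) }
  }
  elites
}

# Draw a replacement genome satisfying the effect limit (discard-and-replace).
replace_within_limit <- function(space, weights) {
  repeat {
    g <- draw_genome(space, weights)
    if (!is.finite(space$effect_limit) ||
        decode(space, g)$total_effects <= space$effect_limit) return(g)
  }
}

#' Single-objective hybrid genetic-algorithm search
#'
#' Runs the penalized single-objective search: random initial population
#' (effect-limit aware), then per generation tournament selection,
#' single-point crossover, one-bit mutation, effect-limit
#' discard-and-replace, evaluation, and elitism with the elites spread
#' round-robin across niche heads.  Every `downhill_period` generations a
#' steepest-descent [downhill()] search is run from the head of each niche
#' and the results replace the worst population members.  The final result
#' is the lowest-fitness record ever evaluated.
#'
#' @param space a [search_space()].
#' @param evaluator evaluator closure ([pk_evaluator()] or
#'   [table_evaluator()]).
#' @param config a [ga_config()].
#' @return list with `best` (`eval_record`), `history` (one row per
#'   evaluated model: generation, genome, ofv, nep, fitness),
#'   `generations` (per-generation best fitness), `population` (final
#'   records), `n_evals`.
#' @export
sohga_search <- function(space, evaluator, config = ga_config()) {
  set.seed(config$rng_seed)
  N <- config$population_size
  weights <- if (is.finite(space$effect_limit))
    calibrate_effect_sampler(space)$weights else tilted_weights(space, 0)
  genomes <- sample_population(space, N)
  pop <- lapply(genomes, evaluator, generation = 1L)
  history <- list(record_rows(pop, 1L))
  gen_best <- numeric(config$num_generations)
  gen_best[1] <- min(vapply(pop, `[[`, numeric(1), "fitness"))
  best <- pop[[order_records(pop)[1]]]
  maybe_downhill <- function(pop, gen) {
    if (gen %% config$downhill_period != 0L) return(pop)
    heads <- niche_heads(pop, config$num_niches, config$niche_radius)
    improved <- lapply(heads, downhill, evaluator = evaluator,
                       two_bit_enabled = config$two_bit_enabled)
    # improved heads replace the worst members, keeping population size
    ord <- rev(order_records(pop))
    keys <- vapply(pop, `[[`, character(1), "key")
    slot <- 1L
    for (r in improved) {
      if (r$key %in% keys) next
      pop[[ord[slot]]] <- r
      keys[ord[slot]] <- r$key
      slot <- slot + 1L
    }
    pop
  }
  pop <- maybe_downhill(pop, 1L)
  if (config$num_generations >= 2L) for (gen in 2:config$num_generations) {
    elites <- pick_elites(pop, config)
    children <- list()
    while (length(children) < N - length(elites)) {
      pa <- tournament_select(pop)
      pb <- tournament_select(pop)
      kids <- crossover(pa$genome, pb$genome, config$crossover_rate)
      for (g in kids) {
        if (length(children) >= N - length(elites)) break
        g <- mutate(g, config$mutation_rate)
        if (is.finite(space$effect_limit) &&
            decode(space, g)$total_effects > space$effect_limit)
          g <- replace_within_limit(space, weights)
        children <- c(children, list(g))
      }
    }
    child_recs <- lapply(children, evaluator, generation = gen)
    pop <- c(elites, child_recs)
    pop <- maybe_downhill(pop, gen)
    history[[gen]] <- record_rows(pop, gen)
    gb <- pop[[order_records(pop)[1]]]
    if (record_before(gb, best)) best <- gb
    gen_best[gen] <- best$fitness
  }
  # lowest-fitness record ever evaluated (downhill included, via the cache)
  all_recs <- evaluated_records(evaluator)
  best <- all_recs[[order_records(all_recs)[1]]]
  list(best = best, history = do.call(rbind, history),
       generations = data.frame(generation = seq_len(config$num_generations),
                                best_fitness = gen_best),
       population = pop, n_evals = evaluator_stats(evaluator)$n_evals,
       config = config)
}

record_rows <- function(records, gen) {
  data.frame(generation = gen,
             genome = vapply(records, `[[`, character(1), "key"),
             ofv = vapply(records, `[[`, numeric(1), "ofv"),
             nep = vapply(records, function(r) if (is.na(r$nep)) NA_integer_
                          else as.integer(r$nep), integer(1)),
             fitness = vapply(records, `[[`, numeric(1), "fitness"))
}

#' Exhaustive enumeration of a small search space
#'
#' Evaluates every one of the `2^n` genomes of an enumerable space; the test
#' oracle for both searches.
#'
#' @param space a [search_space()] with at most `max_bits` bits.
#' @param evaluator evaluator closure.
#' @param max_bits safety cap.
#' @return list of all `eval_record`s.
#' @export
exhaustive_search <- function(space, evaluator, max_bits = 16L) {
  n <- space$n_total_bits
  if (n > max_bits) stop("space too large for exhaustive enumeration")
  lapply(0:(2^n - 1), function(v) {
    bits <- as.integer(intToBits(v)[n:1])
    evaluator(bits)
  })
}
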