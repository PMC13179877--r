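#' Pareto domination on (OFV, NEP)
#'
#' `a` dominates `b` when it is not worse on both objectives and strictly
#' better on at least one (both objectives minimized).
#'
#' @param a,b lists (or records) with elements `ofv` and `nep`.
#' @return logical.
#' @export
dominates <- function(a, b) {
  (a$ofv <= b$ofv && a$nep <= b$nep) && (a$ofv < b$ofv || a$nep < b$nep)
}

objective_matrix <- function(records) {
  cbind(ofv = vapply(records, `[[`, numeric(1), "ofv"),
        nep = vapply(records, function(r) as.numeric(r$nep), numeric(1)))
}

#' Fast non-dominated sorting
#'
#' Computes, for every population member `p`, the domination count `n_p`
#' (solutions dominating `p`) and the dominated set `S_p`.  Members with
#' `n_p = 0` form the first front; peeling then repeatedly decrements `n_q`
#' for `q` in `S_p` of the current front, members reaching zero forming the
#' next front, until all members are ranked.
#'
#' @param objectives an n x 2 matrix (columns `ofv`, `nep`), or a list of
#'   records carrying `ofv` and `nep`.
#' @return list of integer index vectors, one per front in rank order.
#' @export
non_dominated_sort <- function(objectives) {
  if (is.list(objectives) && !is.matrix(objectives))
    objectives <- objective_matrix(objectives)
  n <- nrow(objectives)
  stopifnot(n >= 1L)
  f1 <- objectives[, 1]; f2 <- objectives[, 2]
  n_p <- integer(n)
  S_p <- vector("list", n)
  for (p in seq_len(n)) {
    dom_p <- (f1[p] <= f1 & f2[p] <= f2) & (f1[p] < f1 | f2[p] < f2)
    dom_by <- (f1 <= f1[p] & f2 <= f2[p]) & (f1 < f1[p] | f2 < f2[p])
    S_p[[p]] <- which(dom_p)
    n_p[p] <- sum(dom_by)
  }
  fronts <- list()
  current <- which(n_p == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (p in current) {
      for (q in S_p[[p]]) {
        n_p[q] <- n_p[q] - 1L
        if (n_p[q] == 0L) nxt <- c(nxt, q)
      }
    }
    current <- sort(nxt)
  }
  fronts
}

#' Crowding distance within a front
#'
#' For each objective the front is sorted; boundary members get infinite
#' distance, interior members accumulate the objective-range-normalized gap
#' between their two neighbours, starting from 0.  Fronts of size one or two
#' are all-boundary (all infinite).  When an objective is constant across
#' the front it contributes nothing.
#'
#' @param front an m x 2 objective matrix (or list of records) of mutually
#'   non-dominated members.
#' @return numeric vector of distances aligned with the input order.
#' @export
crowding_distance <- function(front) {
  if (is.list(front) && !is.matrix(front))
    front <- objective_matrix(front)
  m <- nrow(front)
  if (m <= 2L) return(rep(Inf, m))
  d <- numeric(m)
  for (j in seq_len(ncol(front))) {
    ord <- order(front[, j])
    rng <- front[ord[m], j] - front[ord[1], j]
    d[ord[c(1L, m)]] <- Inf
    if (rng > 0)
      for (i in 2:(m - 1L))
        d[ord[i]] <- d[ord[i]] +
          (front[ord[i + 1L], j] - front[ord[i - 1L], j]) / rng
  }
  d
}

#' Environmental selection (combine, sort, truncate)
#'
#' Fills the next population by ascending front rank; the first front that
#' does not fully fit is truncated by descending crowding distance, ties
#' broken by lower NEP then lexicographic bit string.
#'
#' @param pool list of `eval_record`s (parents plus offspring).
#' @param population_size capacity.
#' @return list of kept `eval_record`s.
#' @export
environmental_selection <- function(pool, population_size) {
  stopifnot(length(pool) >= population_size)
  fronts <- non_dominated_sort(pool)
  kept <- integer(0)
  for (fr in fronts) {
    if (length(kept) + length(fr) <= population_size) {
      kept <- c(kept, fr)
      if (length(kept) == population_size) break
    } else {
      # canonicalize the front order first so crowding-distance boundary
      # assignment (and hence selection) is invariant to pool order
      ofv <- vapply(pool[fr], `[[`, numeric(1), "ofv")
      nep <- vapply(pool[fr], function(r) as.numeric(r$nep), numeric(1))
      key <- vapply(pool[fr], `[[`, character(1), "key")
      canon <- order(ofv, nep, key)
      fr <- fr[canon]; nep <- nep[canon]; key <- key[canon]
      cd <- crowding_distance(pool[fr])
      ord <- order(-cd, nep, key)
      kept <- c(kept, fr[ord[seq_len(population_size - length(kept))]])
      break
    }
  }
  pool[kept]
}

# Crowded binary tournament: lower rank wins, then larger crowding
# distance, then lower NEP, then bit string.
crowded_tournament <- function(pop, rank, crowd) {
  if (length(pop) == 1L) return(pop[[1L]])
  i <- sample.int(length(pop), 2L)
  a <- i[1]; b <- i[2]
  pick <- if (rank[a] != rank[b]) {
    if (rank[a] < rank[b]) a else b
  } else if (crowd[a] != crowd[b]) {
    if (crowd[a] > crowd[b]) a else b
  } else if (pop[[a]]$nep != pop[[b]]$nep) {
    if (pop[[a]]$nep < pop[[b]]$nep) a else b
  } else if (pop[[a]]$key <= pop[[b]]$key) a else b
  pop[[pick]]
}

feasible_records <- function(records) {
  records[vapply(records, function(r) isTRUE(r$feasible) && is.finite(r$ofv),
                 logical(1))]
}

#' Pareto front of a set of records
#'
#' Non-dominated subset on (OFV, NEP) with duplicate objective vectors
#' deduplicated, keeping the lexicographically smallest bit string;
#' infeasible records are excluded.  Output is sorted by ascending NEP.
#'
#' @param records list of `eval_record`s.
#' @return list of `eval_record`s (the archive).
#' @export
pareto_front <- function(records) {
  records <- feasible_records(records)
  if (length(records) == 0L) return(list())
  keys <- vapply(records, `[[`, character(1), "key")
  records <- records[order(keys)]
  obj <- objective_matrix(records)
  dup <- duplicated(obj)
  records <- records[!dup]
  obj <- obj[!dup, , drop = FALSE]
  fr1 <- non_dominated_sort(obj)[[1]]
  records <- records[fr1]
  nep <- vapply(records, function(r) as.numeric(r$nep), numeric(1))
  records[order(nep)]
}

#' Multi-objective downhill over a Pareto archive
#'
#' For each archive member, all one-bit neighbours are evaluated; any
#' neighbour not dominated by the current archive is merged and dominated
#' members are pruned.  When a full pass adds nothing and `two_bit_enabled`,
#' one two-bit pass over the archive is made; the search repeats until
#' neither pass adds a member.  The output archive is never dominated by
#' the input archive.
#'
#' @param archive list of mutually non-dominated `eval_record`s.
#' @param evaluator evaluator closure.
#' @param two_bit_enabled logical.
#' @return the improved archive (a [pareto_front()] of all models seen).
#' @export
moo_downhill <- function(archive, evaluator, two_bit_enabled = TRUE) {
  stopifnot(length(archive) >= 1L)
  archive <- pareto_front(archive)
  space <- attr(evaluator, "space")
  admissible <- function(genomes) {
    if (is.null(space) || !is.finite(space$effect_limit)) return(genomes)
    genomes[vapply(genomes, function(g)
      decode(space, g)$total_effects <= space$effect_limit, logical(1))]
  }
  repeat {
    added <- FALSE
    for (neigh_fun in c(list(one_bit_neighbors),
                        if (two_bit_enabled) list(two_bit_neighbors))) {
      cand <- list()
      for (r in archive)
        cand <- c(cand, lapply(admissible(neigh_fun(r$genome)), evaluator))
      merged <- pareto_front(c(archive, cand))
      if (!setequal(vapply(merged, `[[`, character(1), "key"),
                    vapply(archive, `[[`, character(1), "key"))) {
        archive <- merged
        added <- TRUE
        break   # resume one-bit passes after any change
      }
    }
    if (!added) break
  }
  archive
}

#' NSGA-II multi-objective model search
#'
#' Canonical generational NSGA-II over the objectives (OFV, NEP): the
#' initial population is drawn by the effect-limit sampler; each generation
#' creates offspring by crowded binary tournament (front rank, then crowding
#' distance), single-point crossover and one-bit mutation, with offspring
#' exceeding the effect limit discarded before evaluation and replaced; the
#' next population is chosen by [environmental_selection()] over parents
#' and offspring.  Every `downhill_period` generations a [moo_downhill()]
#' pass refines the current rank-1 front.  Diagnostics flags are attached to
#' every record but never enter the objectives.  Environmental selection
#' subsumes elitism, so a configured `elitist_num` is accepted and ignored
#' (with a notice); `num_niches`/`niche_radius` likewise play no role in
#' the multi-objective path.
#'
#' @param space a [search_space()].
#' @param evaluator evaluator closure.
#' @param config a [ga_config()]; published defaults for this path are
#'   population 100 and 30 generations.
#' @return list with `archive` (rank-1 records over all evaluations,
#'   deduplicated, ascending NEP), `final_front` (rank 1 of the final
#'   generation), `history`, `population`, `n_evals`.
#' @export
nsga2_search <- function(space, evaluator,
                         config = ga_config(population_size = 100L,
                                            num_generations = 30L)) {
  set.seed(config$rng_seed)
  if (config$elitist_num > 0L)
    message("nsga2_search: environmental selection subsumes elitism; ",
            "elitist_num is ignored")
  N <- config$population_size
  weights <- if (is.finite(space$effect_limit))
    calibrate_effect_sampler(space)$weights else tilted_weights(space, 0)
  pop <- lapply(sample_population(space, N), evaluator, generation = 1L)
  history <- list(record_rows(pop, 1L))
  run_downhill <- function(pop, gen) {
    if (gen %% config$downhill_period != 0L) return(pop)
    front <- pareto_front(pop)
    if (length(front) == 0L) return(pop)
    improved <- moo_downhill(front, evaluator, config$two_bit_enabled)
    # refreshed front members join the pool; selection restores the size
    environmental_selection(c(pop, improved), N)
  }
  pop <- run_downhill(pop, 1L)
  if (config$num_generations >= 2L) for (gen in 2:config$num_generations) {
    feas <- feasible_records(pop)
    sel_pool <- if (length(feas) >= 2L) feas else pop
    fronts <- non_dominated_sort(sel_pool)
    rank <- integer(length(sel_pool))
    crowd <- numeric(length(sel_pool))
    for (k in seq_along(fronts)) {
      rank[fronts[[k]]] <- k
      crowd[fronts[[k]]] <- crowding_distance(sel_pool[fronts[[k]]])
    }
    children <- list()
    while (length(children) < N) {
      pa <- crowded_tournament(sel_pool, rank, crowd)
      pb <- crowded_tournament(sel_pool, rank, crowd)
      kids <- crossover(pa$genome, pb$genome, config$crossover_rate)
      for (g in kids) {
        if (length(children) >= N) break
        g <- mutate(g, config$mutation_rate)
        if (is.finite(space$effect_limit) &&
            decode(space, g)$total_effects > space$effect_limit)
          g <- replace_within_limit(space, weights)
        children <- c(children, list(g))
      }
    }
    offspring <- lapply(children, evaluator, generation = gen)
    pop <- environmental_selection(c(pop, offspring), N)
    pop <- run_downhill(pop, gen)
    history[[gen]] <- record_rows(pop, gen)
  }
  all_recs <- evaluated_records(evaluator)
  archive <- pareto_front(all_recs)
  list(archive = archive, final_front = pareto_front(pop),
       history = do.call(rbind, history), population = pop,
       n_evals = evaluator_stats(evaluator)$n_evals, config = config)
}

#' Dominated-hypervolume of a two-objective front
#'
#' Area dominated by the front relative to a reference point (worst observed
#' plus one by convention in tests); monotone under archive merges.
#'
#' @param front list of records or an objective matrix.
#' @param ref reference point `c(ofv, nep)`.
#' @return non-negative scalar.
#' @export
hypervolume2d <- function(front, ref) {
  if (is.list(front) && !is.matrix(front)) front <- objective_matrix(front)
  keep <- front[, 1] <= ref[1] & front[, 2] <= ref[2]
  front <- front[keep, , drop = FALSE]
  if (nrow(front) == 0L) return(0)
  front <- front[order(front[, 1]), , drop = FALSE]
  hv <- 0
  prev_nep <- ref[2]
  for (i in seq_len(nrow(front))) {
    nep_i <- min(front[i, 2], prev_nep)
    hv <- hv + (ref[1] - front[i, 1]) * (prev_nep - nep_i)
    prev_nep <- nep_i
  }
  hv
}
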