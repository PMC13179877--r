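# Shared fixtures: small search spaces and deterministic lookup evaluators.

# n_sets token sets, each {0-effect "none", 1-effect option}; the shape used
# for effect-limit calibration checks.
binary_effect_space <- function(n_sets = 6L, effect_limit = 4L) {
  sets <- lapply(seq_len(n_sets), function(i)
    token_set(paste0("set", i), list(
      token_option("none"),
      token_option("effect", n_effects = 1L, n_extra_params = 1L))))
  search_space(sets, effect_limit = effect_limit)
}

genome_value <- function(genome) sum(genome * 2L^((length(genome) - 1L):0L))

# Deterministic OFV surface over an enumerable space, shaped like a model
# selection problem: each chosen option shifts the OFV (some features help,
# some hurt), and a few token-set pairs interact (epistasis, e.g. a BSV
# term only mattering alongside the matching structural feature).  The
# tables are frozen at construction; evaluation never touches the RNG.
make_lookup_evaluator <- function(space, seed = 42L,
                                  penalties = default_penalties()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  nset <- length(space$token_sets)
  main <- lapply(space$token_sets, function(ts)
    c(0, stats::runif(ts$k - 1L, -50, 15)))
  pairs <- if (nset >= 2L) {
    idx <- utils::combn(nset, 2L)
    sel <- sample(ncol(idx), min(3L, ncol(idx)))
    lapply(sel, function(j) list(
      i = idx[1, j], j = idx[2, j],
      w = matrix(stats::runif(space$token_sets[[idx[1, j]]]$k *
                                space$token_sets[[idx[2, j]]]$k, -10, 10),
                 space$token_sets[[idx[1, j]]]$k)))
  } else list()
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  ofv_fun <- function(genome, phen) {
    v <- 1500
    for (i in seq_len(nset)) v <- v + main[[i]][phen$choices[i]]
    for (pr in pairs) v <- v + pr$w[phen$choices[pr$i], phen$choices[pr$j]]
    v
  }
  table_evaluator(space, ofv_fun, penalties = penalties)
}

# Independent brute-force decoder: reads each bit group as an integer and
# applies the modulo rule directly from the token-set table.
reference_decode <- function(space, genome) {
  off <- 0L
  choices <- integer(length(space$token_sets))
  for (i in seq_along(space$token_sets)) {
    ts <- space$token_sets[[i]]
    if (ts$n_bits == 0L) { choices[i] <- 1L; next }
    v <- strtoi(paste(genome[(off + 1):(off + ts$n_bits)], collapse = ""),
                base = 2L)
    choices[i] <- (v %% ts$k) + 1L
    off <- off + ts$n_bits
  }
  choices
}

random_genome <- function(n) sample(0:1, n, replace = TRUE)

# Independent O(N^2) pairwise-domination front assignment: repeatedly strip
# the currently undominated points, applying the domination definition
# directly to every remaining pair.
brute_force_fronts <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    f1 <- obj[remaining, 1]; f2 <- obj[remaining, 2]
    dominated <- vapply(seq_along(remaining), function(p)
      any(f1 <= f1[p] & f2 <= f2[p] & (f1 < f1[p] | f2 < f2[p])),
      logical(1))
    rank[remaining[!dominated]] <- r
    remaining <- remaining[dominated]
  }
  rank
}

# Small rich-design dataset simulated from the example one-compartment oral
# model; memoised per (n_subjects, seed) to keep the suite fast.
example_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(n_subjects = 20L, rng_seed = 7L, sampling = "rich") {
    key <- paste(n_subjects, rng_seed, sampling)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_dataset(
        example_scenario(n_subjects = n_subjects, sampling = sampling,
                         rng_seed = rng_seed))
    cache[[key]]
  }
})
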