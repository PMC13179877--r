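#' Define a token option
#'
#' A token option is one mutually exclusive choice within a token set, e.g.
#' "2 compartments", "power model of weight on CL", or "no covariate".  Its
#' `payload` is a structured description consumed by the model-spec decoder;
#' `n_effects` counts the complexity units the option adds (one additional
#' estimated parameter tied to a feature counts as one effect), and
#' `n_extra_params` counts the thetas/omegas/sigmas it adds.
#'
#' @param label short unique label within the token set.
#' @param payload a list understood by [build_model_spec()], or `NULL` for a
#'   "none/absent" option.
#' @param n_effects non-negative integer number of effects.
#' @param n_extra_params non-negative integer number of added parameters.
#' @return an object of class `token_option`.
#' @export
token_option <- function(label, payload = NULL, n_effects = 0L,
                         n_extra_params = 0L) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  n_effects <- as.integer(n_effects)
  n_extra_params <- as.integer(n_extra_params)
  if (n_effects < 0L || n_extra_params < 0L)
    stop("n_effects and n_extra_params must be non-negative")
  structure(list(label = label, payload = payload,
                 n_effects = n_effects, n_extra_params = n_extra_params),
            class = "token_option")
}

#' Define a token set
#'
#' A token set is an ordered group of mutually exclusive options occupying one
#' bit group of the genome.  The group width is the smallest number of bits
#' `b` with `2^b >= k` for `k` options (0 bits for a single-option set).
#'
#' @param name token-set name, unique within a search space.
#' @param options list of [token_option()] objects (length >= 1).
#' @return an object of class `token_set`.
#' @export
token_set <- function(name, options) {
  stopifnot(is.character(name), length(name) == 1L, length(options) >= 1L)
  ok <- vapply(options, inherits, logical(1), "token_option")
  if (!all(ok)) stop("all options must be token_option objects")
  labels <- vapply(options, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("option labels must be unique within a set")
  k <- length(options)
  n_bits <- if (k == 1L) 0L else as.integer(ceiling(log2(k)))
  structure(list(name = name, options = options, k = k, n_bits = n_bits),
            class = "token_set")
}

#' Define a model search space
#'
#' Token sets are laid out in the genome in declaration order; the genome
#' length is the sum of per-set bit widths.  An optional effect limit caps the
#' total number of effects of candidate models evaluated during a search.
#'
#' @param token_sets list of [token_set()] objects.
#' @param effect_limit positive integer cap on total effects, or `Inf` for
#'   unlimited.
#' @return an object of class `search_space`.
#' @export
search_space <- function(token_sets, effect_limit = Inf) {
  stopifnot(length(token_sets) >= 1L)
  ok <- vapply(token_sets, inherits, logical(1), "token_set")
  if (!all(ok)) stop("token_sets must be a list of token_set objects")
  nm <- vapply(token_sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("token-set names must be unique")
  if (!identical(effect_limit, Inf)) {
    effect_limit <- as.integer(effect_limit)
    if (is.na(effect_limit) || effect_limit < 1L)
      stop("effect_limit must be a positive integer or Inf")
  }
  n_bits <- vapply(token_sets, `[[`, integer(1), "n_bits")
  structure(list(token_sets = token_sets, names = nm,
                 n_bits = n_bits, n_total_bits = sum(n_bits),
                 bit_offsets = cumsum(c(0L, n_bits[-length(n_bits)])),
                 effect_limit = effect_limit),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("search_space:", length(x$token_sets), "token sets,",
      x$n_total_bits, "bits, effect limit",
      if (is.finite(x$effect_limit)) x$effect_limit else "none", "\n")
  for (ts in x$token_sets) {
    cat("  ", ts$name, " [", ts$n_bits, " bits]: ",
        paste(vapply(ts$options, `[[`, character(1), "label"),
              collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

## ---- genomes -------------------------------------------------------------

#' Genome helpers
#'
#' Genomes are plain integer vectors of 0/1 of length `n_total_bits`.
#' `genome_key()` collapses a genome to its bit-string key used for caching
#' and deterministic tie-breaking.
#'
#' @param genome integer vector of 0s and 1s.
#' @return `genome_key()` returns a character scalar such as `"01101"`.
#' @export
genome_key <- function(genome) paste(genome, collapse = "")

#' @rdname genome_key
#' @param key bit-string such as `"01101"`.
#' @export
genome_from_key <- function(key) {
  as.integer(strsplit(key, "", fixed = TRUE)[[1]])
}

check_genome <- function(space, genome) {
  if (length(genome) != space$n_total_bits)
    stop("genome length ", length(genome), " does not match search space (",
         space$n_total_bits, " bits)")
  if (!all(genome %in% c(0L, 1L))) stop("genome bits must be 0 or 1")
  invisible(TRUE)
}

## ---- decoding ------------------------------------------------------------

#' Decode a genome into a phenotype
#'
#' Each token set's bit group (most-significant bit first) is read as an
#' unsigned integer `v`; the chosen option index is `v mod k`, making the
#' decoder total on all `2^n` genomes.  Plain binary coding is used (not Gray
#' code) so that a brute-force table decoder is a trivial oracle.
#'
#' @param space a [search_space()].
#' @param genome integer 0/1 vector of length `n_total_bits`.
#' @return an object of class `phenotype`: list with `choices` (1-based
#'   option index per token set), `total_effects`, `total_extra_params`.
#' @export
decode <- function(space, genome) {
  check_genome(space, genome)
  nset <- length(space$token_sets)
  choices <- integer(nset)
  for (i in seq_len(nset)) {
    ts <- space$token_sets[[i]]
    if (ts$n_bits == 0L) {
      choices[i] <- 1L
      next
    }
    bits <- genome[space$bit_offsets[i] + seq_len(ts$n_bits)]
    v <- sum(bits * 2L^((ts$n_bits - 1L):0L))
    choices[i] <- as.integer(v %% ts$k) + 1L
  }
  opts <- chosen_options(space, choices)
  structure(list(choices = choices,
                 total_effects = sum(vapply(opts, `[[`, integer(1), "n_effects")),
                 total_extra_params =
                   sum(vapply(opts, `[[`, integer(1), "n_extra_params"))),
            class = "phenotype")
}

chosen_options <- function(space, choices) {
  lapply(seq_along(space$token_sets), function(i)
    space$token_sets[[i]]$options[[choices[i]]])
}

#' Total effect count of a phenotype
#'
#' Sums the per-option effect counts of the chosen options; one additional
#' estimated parameter tied to a feature counts as one effect, a
#' "none/absent" option contributes zero.
#'
#' @param phenotype a decoded [decode()] phenotype.
#' @return non-negative integer.
#' @export
count_effects <- function(phenotype) {
  stopifnot(inherits(phenotype, "phenotype"))
  phenotype$total_effects
}

## ---- neighbourhoods ------------------------------------------------------

#' One- and two-bit neighbourhoods of a genome
#'
#' `one_bit_neighbors()` flips each bit in turn (n genomes at Hamming
#' distance 1); `two_bit_neighbors()` flips every pair of bits
#' (n(n-1)/2 genomes at Hamming distance 2).  These neighbourhoods drive the
#' local downhill search.
#'
#' @param genome integer 0/1 vector.
#' @return list of genomes.
#' @export
one_bit_neighbors <- function(genome) {
  lapply(seq_along(genome), function(i) {
    g <- genome
    g[i] <- 1L - g[i]
    g
  })
}

#' @rdname one_bit_neighbors
#' @export
two_bit_neighbors <- function(genome) {
  n <- length(genome)
  if (n < 2L) return(list())
  pairs <- utils::combn(n, 2L)
  lapply(seq_len(ncol(pairs)), function(j) {
    g <- genome
    i <- pairs[, j]
    g[i] <- 1L - g[i]
    g
  })
}

## ---- effect-limit sampling -----------------------------------------------

# Per-set option weights under exponential tilt lambda on effect counts.
tilted_weights <- function(space, lambda) {
  lapply(space$token_sets, function(ts) {
    e <- vapply(ts$options, `[[`, integer(1), "n_effects")
    w <- exp(-lambda * e)
    w / sum(w)
  })
}

# Exact distribution of total effects under independent per-set weights,
# by dynamic-programming convolution (per-set effect counts are tiny).
effect_total_distribution <- function(space, weights) {
  dist <- c(`0` = 1)
  for (i in seq_along(space$token_sets)) {
    ts <- space$token_sets[[i]]
    e <- vapply(ts$options, `[[`, integer(1), "n_effects")
    w <- weights[[i]]
    tot <- as.integer(names(dist))
    new <- numeric(max(tot) + max(e) + 1L)
    for (j in seq_along(e)) {
      idx <- tot + e[j] + 1L
      new[idx] <- new[idx] + dist * w[j]
    }
    names(new) <- 0:(length(new) - 1L)
    dist <- new[new > 0]
  }
  dist
}

p_within_limit <- function(space, lambda) {
  dist <- effect_total_distribution(space, tilted_weights(space, lambda))
  sum(dist[as.integer(names(dist)) <= space$effect_limit])
}

#' Calibrate the effect-limit sampler
#'
#' The raw genome generator weights option `o` within each token set by
#' `exp(-lambda * n_effects(o))`.  `lambda` is found by bisection so that the
#' probability of a freshly generated genome satisfying
#' `total_effects <= effect_limit` equals `target_within` (default 0.80),
#' with the probability computed by exact dynamic-programming convolution of
#' per-set effect counts.  `lambda` may be negative: when the uniform sampler
#' already exceeds the target within-limit fraction, the tilt must favour
#' effect-carrying options to bring the fraction down to the target.
#'
#' @param space a [search_space()] with a finite `effect_limit`.
#' @param target_within target raw within-limit probability.
#' @return list with `lambda`, per-set `weights`, and achieved `p_within`.
#' @export
calibrate_effect_sampler <- function(space, target_within = 0.80) {
  stopifnot(is.finite(space$effect_limit))
  e_min <- sum(vapply(space$token_sets, function(ts)
    min(vapply(ts$options, `[[`, integer(1), "n_effects")), integer(1)))
  e_max <- sum(vapply(space$token_sets, function(ts)
    max(vapply(ts$options, `[[`, integer(1), "n_effects")), integer(1)))
  if (e_min > space$effect_limit)
    stop("infeasible effect limit: no option combination satisfies it")
  if (e_max <= space$effect_limit) {
    # every genome is within the limit; no tilt can change that
    return(list(lambda = 0, weights = tilted_weights(space, 0), p_within = 1))
  }
  # p_within is increasing in lambda; bracket then bisect
  lo <- -1; hi <- 1
  while (p_within_limit(space, lo) > target_within && lo > -60) lo <- lo * 2
  while (p_within_limit(space, hi) < target_within && hi < 60) hi <- hi * 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (p_within_limit(space, mid) < target_within) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  lambda <- (lo + hi) / 2
  list(lambda = lambda, weights = tilted_weights(space, lambda),
       p_within = p_within_limit(space, lambda))
}

# Draw one genome given per-set option weights; the selected option index is
# re-encoded by a uniformly chosen alias value v with v mod k == index - 1,
# so the unlimited (uniform-weight) sampler is uniform over genomes.
draw_genome <- function(space, weights) {
  g <- integer(space$n_total_bits)
  for (i in seq_along(space$token_sets)) {
    ts <- space$token_sets[[i]]
    if (ts$n_bits == 0L) next
    idx <- sample.int(ts$k, 1L, prob = weights[[i]]) - 1L
    aliases <- seq.int(idx, 2L^ts$n_bits - 1L, by = ts$k)
    v <- if (length(aliases) == 1L) aliases else
      aliases[sample.int(length(aliases), 1L)]
    g[space$bit_offsets[i] + seq_len(ts$n_bits)] <-
      (v %/% 2L^((ts$n_bits - 1L):0L)) %% 2L
  }
  g
}

#' Sample an initial population under the effect limit
#'
#' Draws `n` genomes from the calibrated tilted generator (see
#' [calibrate_effect_sampler()]); genomes exceeding the effect limit are
#' discarded before evaluation and replaced by freshly generated ones, so
#' every returned genome satisfies the limit.  The target within-limit
#' fraction (default 80%) is a property of the raw pre-discard generator;
#' raw-generation statistics are attached for inspection.  With an unlimited
#' effect limit the sampler is uniform over option indices.
#'
#' @param space a [search_space()].
#' @param n number of genomes to return.
#' @param target_within raw within-limit target fraction.
#' @return list of `n` genomes with attributes `raw_draws` (total raw
#'   generations), `raw_within` (raw draws within the limit) and `lambda`.
#' @export
sample_population <- function(space, n, target_within = 0.80) {
  stopifnot(n >= 1L)
  unlimited <- !is.finite(space$effect_limit)
  cal <- if (unlimited)
    list(lambda = 0, weights = tilted_weights(space, 0)) else
    calibrate_effect_sampler(space, target_within)
  out <- vector("list", n)
  raw_draws <- 0L
  raw_within <- 0L
  i <- 1L
  while (i <= n) {
    g <- draw_genome(space, cal$weights)
    raw_draws <- raw_draws + 1L
    if (unlimited || decode(space, g)$total_effects <= space$effect_limit) {
      raw_within <- raw_within + 1L
      out[[i]] <- g
      i <- i + 1L
    }
    if (raw_draws > 1000L * n)
      stop("effect-limit rejection rate implausibly high; check calibration")
  }
  attr(out, "raw_draws") <- raw_draws
  attr(out, "raw_within") <- raw_within
  attr(out, "lambda") <- cal$lambda
  out
}

#' Raw within-limit fraction of the calibrated generator
#'
#' Draws `n` genomes from the raw (pre-discard) calibrated generator and
#' returns the fraction whose total effect count is within the space's
#' effect limit.  Used to check the 80% calibration property empirically.
#'
#' @param space a [search_space()] with finite effect limit.
#' @param n number of raw draws.
#' @param target_within calibration target.
#' @return fraction in `[0, 1]`.
#' @export
raw_within_fraction <- function(space, n = 20000L, target_within = 0.80) {
  cal <- calibrate_effect_sampler(space, target_within)
  within <- 0L
  for (i in seq_len(n)) {
    g <- draw_genome(space, cal$weights)
    if (decode(space, g)$total_effects <= space$effect_limit)
      within <- within + 1L
  }
  within / n
}

## ---- search-space files --------------------------------------------------

#' Read a search-space definition file
#'
#' The file (YAML or JSON read by the yaml parser) has the shape:
#' \preformatted{
#' effect_limit: 4        # optional; omit for unlimited
#' token_sets:
#'   - name: compartments
#'     options:
#'       - {label: "1cpt", n_effects: 0, n_extra_params: 0,
#'          payload: {compartments: 1}}
#'       - {label: "2cpt", n_effects: 2, n_extra_params: 2,
#'          payload: {compartments: 2}}
#' }
#' The schema is validated on load; token-set order in the file is the bit
#' order of the genome.
#'
#' @param path file path.
#' @return a [search_space()].
#' @export
read_search_space <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$token_sets)) stop("search-space file must have token_sets")
  sets <- lapply(doc$token_sets, function(ts) {
    if (is.null(ts$name) || is.null(ts$options))
      stop("each token set needs a name and options")
    token_set(ts$name, lapply(ts$options, function(o) {
      if (is.null(o$label)) stop("each option needs a label")
      token_option(o$label, payload = o$payload,
                   n_effects = o$n_effects %||% 0L,
                   n_extra_params = o$n_extra_params %||% 0L)
    }))
  })
  search_space(sets, effect_limit = doc$effect_limit %||% Inf)
}

#' Write a search-space definition file
#'
#' @param space a [search_space()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_search_space <- function(space, path) {
  doc <- list(token_sets = lapply(space$token_sets, function(ts) {
    list(name = ts$name, options = lapply(ts$options, function(o) {
      out <- list(label = o$label, n_effects = o$n_effects,
                  n_extra_params = o$n_extra_params)
      if (!is.null(o$payload)) out$payload <- o$payload
      out
    }))
  }))
  if (is.finite(space$effect_limit)) doc$effect_limit <- space$effect_limit
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
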