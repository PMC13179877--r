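#' Default penalty configuration
#'
#' Points added to the OFV to form the single-objective composite fitness:
#' 10 per estimated theta/omega/sigma, 100 each for convergence failure,
#' covariance-step failure, an absolute estimate correlation above 0.95, and
#' a condition number above 1000.  All values can be overridden.
#'
#' @param theta,omega,sigma points per estimated parameter of each kind.
#' @param convergence,covariance,correlation,condition_number points per
#'   failed diagnostic.
#' @param condition_threshold condition-number failure threshold.
#' @param correlation_threshold strict absolute-correlation threshold.
#' @return a `penalty_config` list.
#' @export
default_penalties <- function(theta = 10, omega = 10, sigma = 10,
                              convergence = 100, covariance = 100,
                              correlation = 100, condition_number = 100,
                              condition_threshold = 1000,
                              correlation_threshold = 0.95) {
  p <- list(theta = theta, omega = omega, sigma = sigma,
            convergence = convergence, covariance = covariance,
            correlation = correlation, condition_number = condition_number,
            condition_threshold = condition_threshold,
            correlation_threshold = correlation_threshold)
  if (any(unlist(p[1:7]) < 0)) stop("penalties must be non-negative")
  if (condition_threshold <= 0 || correlation_threshold <= 0)
    stop("thresholds must be positive")
  class(p) <- "penalty_config"
  p
}

#' Construct a fit-result record directly
#'
#' Builds the same structure as [fit()] returns, from given summary values.
#' Useful for constructing paired records when checking penalty arithmetic
#' and for table-driven evaluators.
#'
#' @param ofv objective function value (-2 log L).
#' @param converged,covariance_ok diagnostic flags.
#' @param correlation_matrix estimation correlation matrix.
#' @param condition_number eigenvalue ratio of the correlation matrix.
#' @param estimates optional [pk_parameters()].
#' @return an object of class `pk_fit`.
#' @export
fit_result <- function(ofv, converged = TRUE, covariance_ok = TRUE,
                       correlation_matrix = diag(2), condition_number = 1,
                       estimates = NULL) {
  structure(list(estimates = estimates, ofv = ofv, converged = converged,
                 covariance_ok = covariance_ok,
                 correlation_matrix = correlation_matrix,
                 condition_number = condition_number,
                 rse = NULL, n_eval = 0L),
            class = "pk_fit")
}

#' Diagnostic flags of a fit
#'
#' Derives the four basic diagnostics from a fit: convergence, covariance
#' step, absence of high estimate correlation (strictly above the
#' threshold), and acceptable condition number.  When the covariance step
#' failed, the correlation and condition checks cannot be computed and are
#' not separately failed (only the covariance penalty applies).
#'
#' @param fit a `pk_fit`.
#' @param penalties a [default_penalties()] configuration (thresholds).
#' @return list of logicals `converged`, `covariance_ok`, `correlation_ok`,
#'   `condition_ok` (`TRUE` = check passed).
#' @export
fit_flags <- function(fit, penalties = default_penalties()) {
  cov_ok <- isTRUE(fit$covariance_ok)
  list(converged = isTRUE(fit$converged),
       covariance_ok = cov_ok,
       correlation_ok = !cov_ok ||
         !correlation_flag(fit$correlation_matrix,
                           penalties$correlation_threshold),
       condition_ok = !cov_ok ||
         fit$condition_number <= penalties$condition_threshold)
}

#' Composite penalized fitness
#'
#' `fitness = OFV + theta_penalty * n_theta + omega_penalty * n_omega +
#' sigma_penalty * n_sigma`, plus 100-point penalties (by default) for each
#' failed diagnostic: non-convergence, covariance-step failure, any absolute
#' off-diagonal estimate correlation strictly above 0.95, and condition
#' number above 1000.  This drives the single-objective hybrid search only;
#' the multi-objective search uses the raw `(OFV, NEP)` pair and ignores
#' penalties and diagnostic flags.
#'
#' @param fit a `pk_fit` (from [fit()] or [fit_result()]).
#' @param spec the [pk_model_spec()], used for parameter counts; ignored
#'   when `counts` is given.
#' @param penalties a [default_penalties()] configuration.
#' @param counts optional list with `n_theta`, `n_omega`, `n_sigma`.
#' @return numeric fitness (>= OFV).
#' @export
composite_fitness <- function(fit, spec = NULL,
                              penalties = default_penalties(),
                              counts = NULL) {
  if (is.null(counts)) {
    if (is.null(spec)) stop("either spec or counts must be supplied")
    counts <- param_counts(spec)
  }
  fl <- fit_flags(fit, penalties)
  fit$ofv +
    penalties$theta * counts$n_theta +
    penalties$omega * counts$n_omega +
    penalties$sigma * counts$n_sigma +
    penalties$convergence * (!fl$converged) +
    penalties$covariance * (!fl$covariance_ok) +
    penalties$correlation * (!fl$correlation_ok) +
    penalties$condition_number * (!fl$condition_ok)
}

## ---- genome -> model spec ------------------------------------------------

#' Build a model spec from a decoded phenotype
#'
#' Merges the payloads of the chosen options into a [pk_model_spec()].
#' Recognized payload entries: `compartments` (1/2/3), `route`, `lag`
#' (logical), `covariate` (list with `parameter`, `covariate`, `form`),
#' `bsv` / `bov` (parameter name), `ruv` (error-model name).  Options with
#' `NULL` payloads contribute nothing ("none/absent" choices).  Payloads
#' inconsistent with each other or with the route (e.g. absorption lag on IV
#' data) raise an error, which [pk_evaluator()] turns into an infeasible
#' record.
#'
#' @param space a [search_space()].
#' @param phenotype a [decode()]d phenotype.
#' @param base list of defaults (`route`, `bsv`, `ruv`, `n_compartments`).
#' @return a [pk_model_spec()].
#' @export
build_model_spec <- function(space, phenotype,
                             base = list(route = "iv_bolus",
                                         bsv = c("CL", "V"),
                                         ruv = "proportional")) {
  n_cpt <- base$n_compartments %||% 1L
  route <- base$route %||% "iv_bolus"
  lag <- isTRUE(base$lag)
  bsv <- base$bsv %||% c("CL", "V")
  bov <- base$bov %||% character()
  ruv <- base$ruv %||% "proportional"
  cov_eff <- base$covariate_effects %||% list()
  for (opt in chosen_options(space, phenotype$choices)) {
    pl <- opt$payload
    if (is.null(pl)) next
    if (!is.null(pl$compartments)) n_cpt <- pl$compartments
    if (!is.null(pl$route)) route <- pl$route
    if (!is.null(pl$lag)) lag <- isTRUE(pl$lag)
    if (!is.null(pl$covariate)) cov_eff <- c(cov_eff, list(pl$covariate))
    if (!is.null(pl$bsv)) bsv <- union(bsv, pl$bsv)
    if (!is.null(pl$bov)) bov <- union(bov, pl$bov)
    if (!is.null(pl$ruv)) ruv <- pl$ruv
  }
  pk_model_spec(n_compartments = n_cpt, route = route, lag = lag,
                covariate_effects = cov_eff, bsv = bsv, bov = bov, ruv = ruv)
}

## ---- evaluators ----------------------------------------------------------

new_eval_record <- function(genome, phenotype, spec, fit, ofv, nep, fitness,
                            flags, feasible = TRUE, generation = NA_integer_,
                            note = "") {
  structure(list(genome = genome, key = genome_key(genome),
                 phenotype = phenotype, spec = spec, fit = fit,
                 ofv = ofv, nep = nep, fitness = fitness, flags = flags,
                 feasible = feasible, generation = generation, note = note),
            class = "eval_record")
}

#' @export
print.eval_record <- function(x, ...) {
  cat("eval_record ", x$key, ": OFV=", format(x$ofv, digits = 8),
      " NEP=", x$nep, " fitness=", format(x$fitness, digits = 8),
      if (!x$feasible) "  [infeasible]" else "", "\n", sep = "")
  invisible(x)
}

make_evaluator <- function(space, eval_fun) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  env$n_calls <- 0L
  f <- function(genome, generation = NA_integer_) {
    key <- genome_key(genome)
    env$n_calls <- env$n_calls + 1L
    hit <- env$cache[[key]]
    if (!is.null(hit)) return(hit)
    env$n_evals <- env$n_evals + 1L
    rec <- eval_fun(genome, generation)
    env$cache[[key]] <- rec
    rec
  }
  attr(f, "env") <- env
  attr(f, "space") <- space
  class(f) <- c("pk_evaluator_fun", class(f))
  f
}

#' Evaluator mapping genomes to fitted evaluation records
#'
#' Returns a caching closure: `evaluator(genome)` decodes the genome, builds
#' the model spec, fits it to the dataset, and returns an `eval_record`
#' carrying the objectives (OFV, NEP), the diagnostic flags and the
#' composite penalized fitness.  Results are cached by the exact bit string,
#' so re-encountered genomes (elitism, downhill) cost nothing.  Genomes
#' decoding to a spec that is infeasible for the dataset yield a record with
#' `fitness = Inf` and `feasible = FALSE` (excluded from Pareto archives)
#' rather than an error.
#'
#' @param space a [search_space()].
#' @param dataset PK dataset.
#' @param penalties a [default_penalties()] configuration.
#' @param method estimation method passed to [fit()].
#' @param base base-spec defaults passed to [build_model_spec()].
#' @param rng_seed seed for the deterministic fit restart jitter.
#' @return an evaluator closure.  See [evaluator_stats()],
#'   [evaluated_records()], [write_run_log()].
#' @export
pk_evaluator <- function(space, dataset, penalties = default_penalties(),
                         method = "foce_i",
                         base = list(route = "iv_bolus"), rng_seed = 1L) {
  make_evaluator(space, function(genome, generation) {
    phen <- decode(space, genome)
    spec <- tryCatch(build_model_spec(space, phen, base),
                     error = function(e) e)
    if (inherits(spec, "error"))
      return(new_eval_record(genome, phen, NULL, NULL, Inf, NA_integer_, Inf,
                             list(converged = FALSE, covariance_ok = FALSE,
                                  correlation_ok = FALSE, condition_ok = FALSE),
                             feasible = FALSE, generation = generation,
                             note = conditionMessage(spec)))
    ft <- tryCatch(fit(spec, dataset, method = method, rng_seed = rng_seed),
                   error = function(e) e)
    if (inherits(ft, "error") || !is.finite(ft$ofv))
      return(new_eval_record(genome, phen, spec, NULL, Inf, nep(spec), Inf,
                             list(converged = FALSE, covariance_ok = FALSE,
                                  correlation_ok = FALSE, condition_ok = FALSE),
                             feasible = FALSE, generation = generation,
                             note = if (inherits(ft, "error"))
                               conditionMessage(ft) else "non-finite OFV"))
    new_eval_record(genome, phen, spec, ft, ft$ofv, nep(spec),
                    composite_fitness(ft, spec, penalties),
                    fit_flags(ft, penalties),
                    generation = generation)
  })
}

#' Table-driven evaluator for enumerable benchmark spaces
#'
#' Deterministic evaluator used for oracle tests and algorithm benchmarking:
#' the OFV is `ofv_fun(genome, phenotype)` and the NEP is a base count plus
#' the phenotype's extra parameters.  All diagnostics pass, so the composite
#' fitness is `ofv + theta_penalty * nep`.
#'
#' @param space a [search_space()].
#' @param ofv_fun function of `(genome, phenotype)` returning a scalar OFV.
#' @param penalties a [default_penalties()] configuration.
#' @param base_nep parameters of the minimal model in the space.
#' @return an evaluator closure.
#' @export
table_evaluator <- function(space, ofv_fun, penalties = default_penalties(),
                            base_nep = 3L) {
  make_evaluator(space, function(genome, generation) {
    phen <- decode(space, genome)
    ofv <- ofv_fun(genome, phen)
    nep <- base_nep + phen$total_extra_params
    ft <- fit_result(ofv)
    new_eval_record(genome, phen, NULL, ft, ofv, nep,
                    ofv + penalties$theta * nep,
                    fit_flags(ft, penalties), generation = generation)
  })
}

#' Evaluator bookkeeping
#'
#' `evaluator_stats()` reports calls, actual evaluations (cache misses) and
#' cache size; `evaluated_records()` returns every cached record;
#' `write_run_log()` writes the one-line-per-model CSV run log (generation,
#' bit string, OFV, NEP, fitness, flags).
#'
#' @param evaluator an evaluator closure.
#' @return see above.
#' @export
evaluator_stats <- function(evaluator) {
  env <- attr(evaluator, "env")
  list(n_calls = env$n_calls, n_evals = env$n_evals,
       cache_size = length(ls(env$cache)))
}

#' @rdname evaluator_stats
#' @export
evaluated_records <- function(evaluator) {
  env <- attr(evaluator, "env")
  recs <- lapply(sort(ls(env$cache)), function(k) env$cache[[k]])
  recs
}

#' @rdname evaluator_stats
#' @param path CSV output path.
#' @export
write_run_log <- function(evaluator, path) {
  recs <- evaluated_records(evaluator)
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(generation = r$generation, genome = r$key, ofv = r$ofv,
               nep = r$nep, fitness = r$fitness, feasible = r$feasible,
               converged = r$flags$converged,
               covariance_ok = r$flags$covariance_ok,
               correlation_ok = r$flags$correlation_ok,
               condition_ok = r$flags$condition_ok)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
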