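#' Define a simulation scenario
#'
#' A scenario fixes everything needed to simulate a PK dataset from a known
#' true model: cohort size, dosing schedule, a rich or sparse sampling
#' design, covariate distributions, the true model spec and parameters, and
#' the occasion structure for between-occasion variability.  Rich designs
#' observe every subject at >= 15 nominal times; sparse designs draw 1-3
#' random times per subject within the last dosing interval, emulating
#' therapeutic-drug-monitoring data.
#'
#' @param truth_spec true [pk_model_spec()].
#' @param truth_params true [pk_parameters()].
#' @param n_subjects cohort size.
#' @param dose_amount dose amount, a single number or a sampling function
#'   `function(n)`.
#' @param n_doses number of doses per subject.
#' @param dose_interval dosing interval (h) for multiple dosing.
#' @param sampling `"rich"` or `"sparse"`.
#' @param rich_times nominal sampling times after the last dose (rich
#'   designs; length >= 15 by default).
#' @param sparse_n_range inclusive range of per-subject sample counts for
#'   sparse designs.
#' @param covariates named list of covariate distributions, each a list with
#'   `dist` in `lognormal` (meanlog, sdlog), `uniform` (min, max),
#'   `normal` (mean, sd) or `bernoulli` (p).
#' @param occasions number of occasions (>= 2 required when the truth has
#'   BOV terms); occasions split the dose sequence into consecutive blocks.
#' @param rng_seed simulation seed.
#' @return a `pk_scenario` object.
#' @export
pk_scenario <- function(truth_spec, truth_params,
                        n_subjects = 50L,
                        dose_amount = 100,
                        n_doses = 1L,
                        dose_interval = 12,
                        sampling = c("rich", "sparse"),
                        rich_times = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10,
                                       12, 16, 24, 36, 48),
                        sparse_n_range = c(1L, 3L),
                        covariates = list(),
                        occasions = 1L,
                        rng_seed = 1L) {
  sampling <- match.arg(sampling)
  stopifnot(n_subjects >= 1L, n_doses >= 1L)
  if (length(truth_spec$bov) && occasions < 2L)
    stop("BOV in the true model requires at least 2 occasions")
  if (occasions > n_doses)
    stop("occasions cannot exceed the number of doses")
  for (ce in truth_spec$covariate_effects)
    if (!ce$covariate %in% names(covariates))
      stop("true model uses covariate ", ce$covariate,
           " with no distribution in the scenario")
  structure(list(truth_spec = truth_spec, truth_params = truth_params,
                 n_subjects = as.integer(n_subjects),
                 dose_amount = dose_amount, n_doses = as.integer(n_doses),
                 dose_interval = dose_interval, sampling = sampling,
                 rich_times = rich_times,
                 sparse_n_range = as.integer(sparse_n_range),
                 covariates = covariates, occasions = as.integer(occasions),
                 rng_seed = as.integer(rng_seed)),
            class = "pk_scenario")
}

draw_covariate <- function(cfg, n) {
  switch(cfg$dist,
         lognormal = stats::rlnorm(n, cfg$meanlog, cfg$sdlog),
         uniform = stats::runif(n, cfg$min, cfg$max),
         normal = stats::rnorm(n, cfg$mean, cfg$sd),
         bernoulli = stats::rbinom(n, 1L, cfg$p),
         stop("unknown covariate distribution ", cfg$dist))
}

add_ruv <- function(ruv, sigma, f) {
  n <- length(f)
  switch(ruv,
         additive = f + stats::rnorm(n, 0, sqrt(sigma[["add"]])),
         proportional = f * (1 + stats::rnorm(n, 0, sqrt(sigma[["prop"]]))),
         combined = f * (1 + stats::rnorm(n, 0, sqrt(sigma[["prop"]]))) +
           stats::rnorm(n, 0, sqrt(sigma[["add"]])))
}

#' Simulate a PK dataset from a scenario
#'
#' Per subject: draws covariates, BSV deviates (and per-occasion BOV
#' deviates), computes individual parameters through the true covariate
#' model, predicts concentrations with the PK engine, and adds residual
#' error per the true residual model.  Proportional and combined errors are
#' multiplicative around the prediction; additive errors can produce
#' negative observations, which are retained.  The result is a NONMEM-style
#' data frame plus a truth record (spec, parameters, covariate references,
#' seed) suitable for recovery checks.
#'
#' @param scenario a [pk_scenario()].
#' @return list with `data` (data frame: ID, TIME, AMT, EVID, MDV, DV,
#'   optional OCC, covariates) and `truth`.
#' @export
generate_dataset <- function(scenario) {
  set.seed(scenario$rng_seed)
  spec <- scenario$truth_spec
  par <- scenario$truth_params
  n <- scenario$n_subjects
  covs <- lapply(scenario$covariates, draw_covariate, n = n)
  dose_t <- (seq_len(scenario$n_doses) - 1L) * scenario$dose_interval
  last_dose <- dose_t[scenario$n_doses]
  # continuous covariates centered at the simulated cohort median, matching
  # the estimation-side convention
  refs <- numeric(0)
  for (ce in spec$covariate_effects)
    refs[ce$covariate] <- if (ce$form == "proportional_shift") 0 else
      stats::median(covs[[ce$covariate]])
  occ_of_dose <- as.integer(ceiling(seq_len(scenario$n_doses) /
                                      (scenario$n_doses / scenario$occasions)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    amt <- if (is.function(scenario$dose_amount))
      scenario$dose_amount(1L) else scenario$dose_amount
    times <- if (scenario$sampling == "rich") {
      last_dose + scenario$rich_times
    } else {
      k <- sample(seq(scenario$sparse_n_range[1], scenario$sparse_n_range[2]),
                  1L)
      sort(last_dose + stats::runif(k, 0, scenario$dose_interval))
    }
    eta <- if (length(spec$bsv))
      stats::setNames(stats::rnorm(length(spec$bsv), 0,
                                   sqrt(par$omega[paste0("BSV_", spec$bsv)])),
                      spec$bsv) else NULL
    sub_covs <- lapply(covs, `[`, i)
    obs_occ <- vapply(times, function(tt)
      occ_of_dose[max(which(dose_t <= tt))], integer(1))
    f <- numeric(length(times))
    for (oc in unique(obs_occ)) {
      kap <- if (length(spec$bov))
        stats::setNames(stats::rnorm(length(spec$bov), 0,
                                     sqrt(par$omega[paste0("BOV_", spec$bov)])),
                        spec$bov) else NULL
      p_i <- individual_params(spec, par$theta, sub_covs, refs, eta, kap)
      sel <- obs_occ == oc
      f[sel] <- predict_conc(spec, p_i,
                             data.frame(time = dose_t, amt = amt), times[sel])
    }
    dv <- add_ruv(spec$ruv, par$sigma, f)
    sub <- rbind(
      data.frame(ID = i, TIME = dose_t, AMT = amt, EVID = 1L, MDV = 1L,
                 DV = NA_real_, OCC = occ_of_dose),
      data.frame(ID = i, TIME = times, AMT = 0, EVID = 0L, MDV = 0L,
                 DV = dv, OCC = obs_occ))
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    for (nm in names(sub_covs)) sub[[nm]] <- sub_covs[[nm]]
    rows[[i]] <- sub
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  if (scenario$occasions == 1L) data$OCC <- NULL
  list(data = data,
       truth = list(spec = spec, params = par, refs = refs,
                    rng_seed = scenario$rng_seed))
}

#' Write the truth sidecar of a simulated dataset
#'
#' YAML file recording the generating model, parameter values, covariate
#' reference values and seed, so covariate-effect and parameter recovery
#' can be checked against it.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  spec <- truth$spec
  yaml::write_yaml(list(
    model = list(n_compartments = spec$n_compartments, route = spec$route,
                 lag = spec$lag, covariate_effects = spec$covariate_effects,
                 bsv = spec$bsv, bov = spec$bov, ruv = spec$ruv),
    theta = as.list(truth$params$theta),
    omega = as.list(truth$params$omega),
    sigma = as.list(truth$params$sigma),
    covariate_refs = as.list(truth$refs),
    rng_seed = truth$rng_seed), path)
  invisible(path)
}

#' Re-simulate observations on an existing design
#'
#' Draws fresh BSV/BOV deviates and residual errors for every subject of
#' `dataset`, keeping dose history, sampling times and covariates fixed.
#' This is the replicate simulator behind the visual predictive check.
#' Uses the current RNG state (seed outside).
#'
#' @param spec a [pk_model_spec()].
#' @param params a [pk_parameters()].
#' @param dataset PK dataset providing the design.
#' @param refs covariate reference values; defaults to
#'   [covariate_refs()] of `dataset`.
#' @return numeric vector of simulated DV for the observation rows of
#'   `dataset` (in dataset order).
#' @export
simulate_dv <- function(spec, params, dataset, refs = NULL) {
  refs <- refs %||% covariate_refs(spec, dataset)
  subs <- prepare_subjects(spec, dataset)
  is_obs <- dataset$EVID == 0 & dataset$MDV == 0 & !is.na(dataset$DV)
  obs_rows <- split(which(is_obs), dataset$ID[is_obs])
  sim <- simulate_dv_prepped(spec, params, subs, refs)
  # map each subject's simulated values back to the original row positions
  dv <- rep(NA_real_, nrow(dataset))
  for (nm in names(sim)) dv[obs_rows[[nm]]] <- sim[[nm]]
  dv[is_obs]
}

# replicate simulator on pre-split subjects (hot path of the pcVPC)
simulate_dv_prepped <- function(spec, params, subs, refs) {
  lapply(subs, function(sub) {
    eta <- if (length(spec$bsv))
      stats::setNames(stats::rnorm(length(spec$bsv), 0,
                                   sqrt(params$omega[paste0("BSV_", spec$bsv)])),
                      spec$bsv) else NULL
    f <- numeric(length(sub$times))
    for (oc in sub$occasions) {
      sel <- sub$occ == oc
      if (!any(sel)) next
      kap <- if (length(spec$bov))
        stats::setNames(stats::rnorm(length(spec$bov), 0,
                                     sqrt(params$omega[paste0("BOV_", spec$bov)])),
                        spec$bov) else NULL
      p_i <- individual_params(spec, params$theta, sub$covs, refs, eta, kap)
      f[sel] <- predict_conc(spec, p_i, sub$doses, sub$times[sel])
    }
    add_ruv(spec$ruv, params$sigma, f)
  })
}

## ---- benchmark spaces ----------------------------------------------------

opt_none <- function() token_option("none")

cov_set <- function(name, parameter, covariate, form, discrete = FALSE) {
  token_set(name, list(
    opt_none(),
    token_option(form, payload = list(covariate = list(
      parameter = parameter, covariate = covariate,
      form = if (discrete) "proportional_shift" else form)),
      n_effects = 1L, n_extra_params = 1L)))
}

bsv_set <- function(parameter) {
  token_set(paste0("bsv_", parameter), list(
    opt_none(),
    token_option(paste0("BSV ", parameter),
                 payload = list(bsv = parameter),
                 n_effects = 1L, n_extra_params = 1L)))
}

ruv_set <- function() {
  token_set("ruv", list(
    token_option("proportional", payload = list(ruv = "proportional"),
                 n_effects = 0L, n_extra_params = 1L),
    token_option("additive", payload = list(ruv = "additive"),
                 n_effects = 0L, n_extra_params = 1L),
    token_option("combined", payload = list(ruv = "combined"),
                 n_effects = 1L, n_extra_params = 2L)))
}

#' Benchmark search spaces
#'
#' `"tiny"` is a 10-bit, fully enumerable oral search space (1024 genomes)
#' used with table-driven evaluators as the exhaustive-search oracle.
#' `"table3_like"` mirrors the shape of one published compound search:
#' compartment count, covariate effects with per-option effect counts, BSV
#' subsets, residual error forms, and absorption options, with the
#' compound's effect limit.
#'
#' @param kind `"tiny"` or `"table3_like"`.
#' @param compound for `"table3_like"`: `"quetiapine"`, `"ziprasidone"`,
#'   `"clozapine"` or `"dmag"`.
#' @return a [search_space()].
#' @export
make_benchmark_space <- function(kind = c("tiny", "table3_like"),
                                 compound = "quetiapine") {
  kind <- match.arg(kind)
  if (kind == "tiny") {
    return(search_space(list(
      token_set("compartments", list(
        token_option("1cpt", payload = list(compartments = 1L)),
        token_option("2cpt", payload = list(compartments = 2L),
                     n_effects = 2L, n_extra_params = 2L))),
      cov_set("wt_cl", "CL", "WT", "power"),
      cov_set("age_cl", "CL", "AGE", "power"),
      cov_set("sex_v", "V", "SEX", "proportional_shift", discrete = TRUE),
      cov_set("wt_v", "V", "WT", "power"),
      bsv_set("KA"),
      token_set("lag", list(
        opt_none(),
        token_option("lag", payload = list(lag = TRUE),
                     n_effects = 1L, n_extra_params = 1L))),
      ruv_set(),
      bsv_set("V"))))
  }
  compound <- match.arg(compound,
                        c("quetiapine", "ziprasidone", "clozapine", "dmag"))
  cpt3 <- token_set("compartments", list(
    token_option("1cpt", payload = list(compartments = 1L)),
    token_option("2cpt", payload = list(compartments = 2L),
                 n_effects = 2L, n_extra_params = 2L),
    token_option("3cpt", payload = list(compartments = 3L),
                 n_effects = 4L, n_extra_params = 4L)))
  cpt2 <- token_set("compartments", list(
    token_option("1cpt", payload = list(compartments = 1L)),
    token_option("2cpt", payload = list(compartments = 2L),
                 n_effects = 2L, n_extra_params = 2L)))
  lag_set <- token_set("absorption", list(
    token_option("first_order"),
    token_option("first_order_lag", payload = list(lag = TRUE),
                 n_effects = 1L, n_extra_params = 1L)))
  sets <- switch(compound,
    quetiapine = list(cpt3,
      cov_set("age_cl", "CL", "AGE", "power"),
      cov_set("wt_cl", "CL", "WT", "power"),
      cov_set("wt_v", "V", "WT", "power"),
      cov_set("sex_cl", "CL", "SEX", "proportional_shift", TRUE),
      cov_set("smok_cl", "CL", "SMOK", "proportional_shift", TRUE),
      bsv_set("V"), bsv_set("Q2"), bsv_set("V2"),
      ruv_set(), lag_set),
    ziprasidone = list(cpt2,
      cov_set("age_cl", "CL", "AGE", "power"),
      cov_set("wt_cl", "CL", "WT", "power"),
      cov_set("wt_v", "V", "WT", "power"),
      cov_set("sex_cl", "CL", "SEX", "proportional_shift", TRUE),
      cov_set("race_cl", "CL", "RACE", "proportional_shift", TRUE),
      cov_set("conmed_cl", "CL", "CONMED", "proportional_shift", TRUE),
      bsv_set("V"), bsv_set("KA"), ruv_set(), lag_set),
    clozapine = list(cpt2,
      cov_set("age_cl", "CL", "AGE", "power"),
      cov_set("wt_cl", "CL", "WT", "power"),
      cov_set("ht_cl", "CL", "HT", "power"),
      cov_set("sex_cl", "CL", "SEX", "proportional_shift", TRUE),
      cov_set("form_cl", "CL", "FORM", "proportional_shift", TRUE),
      bsv_set("V"), ruv_set()),
    dmag = list(cpt3,
      cov_set("age_cl", "CL", "AGE", "power"),
      cov_set("wt_cl", "CL", "WT", "power"),
      cov_set("crea_cl", "CL", "CREA", "power"),
      cov_set("wt_v", "V", "WT", "power"),
      cov_set("sex_cl", "CL", "SEX", "proportional_shift", TRUE),
      bsv_set("V"),
      token_set("bov_v", list(
        opt_none(),
        token_option("BOV V", payload = list(bov = "V"),
                     n_effects = 1L, n_extra_params = 1L))),
      token_set("bov_cl", list(
        opt_none(),
        token_option("BOV CL", payload = list(bov = "CL"),
                     n_effects = 1L, n_extra_params = 1L))),
      ruv_set()))
  limit <- switch(compound, quetiapine = 6L, dmag = 6L,
                  ziprasidone = 4L, clozapine = 4L)
  search_space(sets, effect_limit = limit)
}

#' A small true model and scenario used throughout examples and tests
#'
#' One-compartment oral model, CL 5 L/h, V 50 L, KA 1.2 /h, 15% BSV on CL
#' and V, 10% proportional residual error; 50 subjects, single 100 mg dose,
#' rich sampling (15 nominal times).
#'
#' @param n_subjects cohort size.
#' @param sampling `"rich"` or `"sparse"`.
#' @param rng_seed simulation seed.
#' @return a [pk_scenario()].
#' @export
example_scenario <- function(n_subjects = 50L, sampling = "rich",
                             rng_seed = 1L) {
  spec <- pk_model_spec(1L, route = "oral_first_order", bsv = c("CL", "V"),
                        ruv = "proportional")
  params <- pk_parameters(
    theta = c(CL = 5, V = 50, KA = 1.2),
    omega = c(BSV_CL = 0.15^2, BSV_V = 0.15^2),
    sigma = c(prop = 0.10^2))
  pk_scenario(spec, params, n_subjects = n_subjects, dose_amount = 100,
              sampling = sampling,
              rich_times = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16,
                             24, 36, 48),
              rng_seed = rng_seed)
}
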