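#' Prediction-corrected visual predictive check
#'
#' Computes a pcVPC table for a model on a dataset.  The population
#' prediction `PRED` (random effects at zero, covariates included) is
#' computed per observation row; rows with `PRED = 0` are excluded (with a
#' message giving the count).  Observations are binned into time bins with
#' (by default) equal observation counts, and each observed or simulated
#' value is prediction-corrected as `pcY = Y * median(PRED in bin) / PRED`.
#' `n_replicates` full-dataset simulations under the model give, per bin,
#' the across-replicate median and 90% interval of each simulated
#' percentile.  Percentiles use the linear-interpolation estimator
#' (`quantile` type 7) so tables are bit-reproducible under a fixed seed.
#'
#' @param dataset PK dataset with observations.
#' @param spec a [pk_model_spec()].
#' @param fitted_params a [pk_parameters()] (typically fitted estimates).
#' @param n_replicates number of simulation replicates (published runs used
#'   1000).
#' @param n_bins number of quantile-based time bins.
#' @param rng_seed simulation seed.
#' @param probs observed/simulated percentiles summarized per bin.
#' @param ci across-replicate interval coverage for each percentile.
#' @return an object of class `vpc_table`: data frame with one row per bin:
#'   time bounds and midpoint, `n_obs`, observed percentiles (`obs_p5`,
#'   `obs_p50`, `obs_p95`), and for each simulated percentile its
#'   across-replicate median, lower and upper interval bounds
#'   (`sim_p50_med`, `sim_p50_lo`, `sim_p50_hi`, ...).
#' @export
pcvpc <- function(dataset, spec, fitted_params, n_replicates = 1000L,
                  n_bins = 8L, rng_seed = 1L, probs = c(0.05, 0.5, 0.95),
                  ci = 0.90) {
  is_obs <- dataset$EVID == 0 & dataset$MDV == 0 & !is.na(dataset$DV)
  if (!any(is_obs)) stop("dataset has no observations")
  refs <- covariate_refs(spec, dataset)
  subs <- prepare_subjects(spec, dataset)
  pred <- unlist(lapply(subs, function(sub) {
    p_i <- individual_params(spec, fitted_params$theta, sub$covs, refs)
    predict_conc(spec, p_i, sub$doses, sub$times)
  }), use.names = FALSE)
  # reassemble PRED in dataset observation-row order
  obs_rows <- split(which(is_obs), dataset$ID[is_obs])
  pred_full <- rep(NA_real_, nrow(dataset))
  k <- 0L
  for (nm in names(subs)) {
    n_i <- length(subs[[nm]]$times)
    pred_full[obs_rows[[nm]]] <- pred[k + seq_len(n_i)]
    k <- k + n_i
  }
  pred <- pred_full[is_obs]
  time <- dataset$TIME[is_obs]
  y <- dataset$DV[is_obs]
  drop <- pred == 0
  if (any(drop)) {
    message("pcvpc: excluding ", sum(drop), " observation(s) with PRED = 0")
    time <- time[!drop]; y <- y[!drop]; pred <- pred[!drop]
  }
  breaks <- unique(stats::quantile(time, probs = seq(0, 1,
                                                     length.out = n_bins + 1),
                                   type = 7, names = FALSE))
  if (length(breaks) < 2L) breaks <- range(time) + c(-1e-9, 1e-9)
  bin <- cut(time, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  nb <- max(bin)
  pc_factor <- numeric(length(pred))
  for (b in seq_len(nb))
    pc_factor[bin == b] <- stats::median(pred[bin == b]) / pred[bin == b]
  q3 <- function(x) stats::quantile(x, probs = probs, type = 7, names = FALSE)
  obs_q <- vapply(seq_len(nb), function(b) q3(y[bin == b] * pc_factor[bin == b]),
                  numeric(length(probs)))
  set.seed(rng_seed)
  sim_q <- array(NA_real_, c(n_replicates, length(probs), nb))
  sim_dv <- rep(NA_real_, nrow(dataset))
  bin_idx <- lapply(seq_len(nb), function(b) which(bin == b))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_dv_prepped(spec, fitted_params, subs, refs)
    for (nm in names(sim)) sim_dv[obs_rows[[nm]]] <- sim[[nm]]
    ysim <- sim_dv[is_obs][!drop]
    for (b in seq_len(nb))
      sim_q[r, , b] <- q3(ysim[bin_idx[[b]]] * pc_factor[bin_idx[[b]]])
  }
  alpha <- (1 - ci) / 2
  summ <- function(v) stats::quantile(v, probs = c(alpha, 0.5, 1 - alpha),
                                      type = 7, names = FALSE)
  out <- data.frame(bin = seq_len(nb),
                    t_lo = breaks[-length(breaks)][seq_len(nb)],
                    t_hi = breaks[-1][seq_len(nb)],
                    t_mid = vapply(seq_len(nb), function(b)
                      stats::median(time[bin == b]), numeric(1)),
                    n_obs = as.integer(table(factor(bin, seq_len(nb)))))
  lbl <- paste0("p", probs * 100)
  for (j in seq_along(probs)) out[[paste0("obs_", lbl[j])]] <- obs_q[j, ]
  for (j in seq_along(probs)) {
    s <- vapply(seq_len(nb), function(b) summ(sim_q[, j, b]), numeric(3))
    out[[paste0("sim_", lbl[j], "_lo")]] <- s[1, ]
    out[[paste0("sim_", lbl[j], "_med")]] <- s[2, ]
    out[[paste0("sim_", lbl[j], "_hi")]] <- s[3, ]
  }
  class(out) <- c("vpc_table", "data.frame")
  attr(out, "n_replicates") <- n_replicates
  attr(out, "ci") <- ci
  out
}

#' Report a Pareto archive
#'
#' One row per archive member, sorted by ascending NEP: bit string, decoded
#' phenotype summary, OFV, NEP and the four diagnostic flags.  With
#' `pass_only = TRUE` only models passing all basic diagnostics are kept
#' (the "passed basic diagnostic criteria" view).  The `(NEP, OFV)` columns
#' are the scatter data of the front staircase plot.
#'
#' @param archive list of `eval_record`s (e.g. from [nsga2_search()]).
#' @param pass_only drop records with any failed diagnostic flag.
#' @return data frame of class `pareto_report`.
#' @export
pareto_report <- function(archive, pass_only = FALSE) {
  stopifnot(length(archive) >= 1L)
  df <- do.call(rbind, lapply(archive, function(r)
    data.frame(genome = r$key, nep = as.integer(r$nep), ofv = r$ofv,
               model = if (!is.null(r$spec)) describe_spec(r$spec) else "",
               converged = r$flags$converged,
               covariance_ok = r$flags$covariance_ok,
               correlation_ok = r$flags$correlation_ok,
               condition_ok = r$flags$condition_ok,
               generation = r$generation)))
  if (pass_only)
    df <- df[df$converged & df$covariance_ok & df$correlation_ok &
               df$condition_ok, , drop = FALSE]
  df <- df[order(df$nep, df$ofv, df$genome), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pareto_report", "data.frame")
  df
}

describe_spec <- function(spec) {
  paste0(spec$n_compartments, "cpt ",
         if (spec$route == "oral_first_order") "oral" else "iv",
         if (spec$lag) "+lag" else "",
         if (length(spec$covariate_effects))
           paste0(" | ", paste(vapply(spec$covariate_effects, function(ce)
             paste0(ce$covariate, ">", ce$parameter), character(1)),
             collapse = ",")) else "",
         " | BSV:", paste(spec$bsv, collapse = ","),
         if (length(spec$bov))
           paste0(" BOV:", paste(spec$bov, collapse = ",")) else "",
         " | ", spec$ruv)
}

#' Merge Pareto archives from separate runs
#'
#' Combines the records and recomputes the non-dominated front; the merged
#' front is never dominated by either input.
#'
#' @param ... lists of `eval_record`s.
#' @return merged archive (a [pareto_front()]).
#' @export
merge_archives <- function(...) {
  pareto_front(do.call(c, list(...)))
}

#' Write a run manifest
#'
#' Records seed, configuration and package version for a search run.
#'
#' @param path output YAML path.
#' @param config a [ga_config()].
#' @param extra named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, extra = list()) {
  yaml::write_yaml(c(list(
    package = "pkmoo",
    version = as.character(utils::packageVersion("pkmoo")),
    config = unclass(config)), extra), path)
  invisible(path)
}
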