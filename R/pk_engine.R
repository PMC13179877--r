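#' Specify a candidate population PK model
#'
#' A `pk_model_spec` is the decoded phenotype of one candidate model: linear
#' 1-3 compartment disposition, IV bolus or first-order oral absorption
#' (optionally with an absorption lag), covariate effects on structural
#' parameters, log-normal between-subject (BSV) and between-occasion (BOV)
#' variability on chosen parameters, and an additive, proportional or
#' combined residual error model.
#'
#' @param n_compartments 1, 2 or 3.
#' @param route `"iv_bolus"` or `"oral_first_order"`.
#' @param lag logical; absorption lag time (oral only).
#' @param covariate_effects list of `list(parameter=, covariate=, form=)`
#'   where `form` is one of `"power"`, `"linear"`, `"exponential"`
#'   (continuous covariates) or `"proportional_shift"` (discrete 0/1).
#' @param bsv character vector of structural parameters carrying BSV.
#' @param bov character vector of structural parameters carrying BOV
#'   (requires an `OCC` column in the dataset).
#' @param ruv `"proportional"`, `"additive"` or `"combined"`.
#' @return an object of class `pk_model_spec`.
#' @export
pk_model_spec <- function(n_compartments = 1L,
                          route = c("iv_bolus", "oral_first_order"),
                          lag = FALSE,
                          covariate_effects = list(),
                          bsv = c("CL", "V"),
                          bov = character(),
                          ruv = c("proportional", "additive", "combined")) {
  route <- match.arg(route)
  ruv <- match.arg(ruv)
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% 1:3) stop("n_compartments must be 1, 2 or 3")
  if (lag && route != "oral_first_order")
    stop("absorption lag requires the oral route")
  sp <- structural_parameter_names(n_compartments, route, lag)
  bad <- setdiff(c(bsv, bov), sp)
  if (length(bad))
    stop("BSV/BOV on parameters absent from the structural model: ",
         paste(bad, collapse = ", "))
  for (ce in covariate_effects) {
    if (!all(c("parameter", "covariate", "form") %in% names(ce)))
      stop("each covariate effect needs parameter, covariate and form")
    if (!ce$parameter %in% sp)
      stop("covariate effect on unknown parameter ", ce$parameter)
    if (!ce$form %in% c("power", "linear", "exponential", "proportional_shift"))
      stop("unknown covariate form ", ce$form)
  }
  structure(list(n_compartments = n_compartments, route = route, lag = lag,
                 covariate_effects = covariate_effects,
                 bsv = bsv, bov = bov, ruv = ruv),
            class = "pk_model_spec")
}

structural_parameter_names <- function(n_compartments, route, lag) {
  p <- c("CL", "V")
  if (n_compartments >= 2L) p <- c(p, "Q2", "V2")
  if (n_compartments == 3L) p <- c(p, "Q3", "V3")
  if (route == "oral_first_order") p <- c(p, "KA")
  if (lag) p <- c(p, "ALAG")
  p
}

#' @export
print.pk_model_spec <- function(x, ...) {
  cov_txt <- if (length(x$covariate_effects) == 0) "none" else
    paste(vapply(x$covariate_effects, function(ce)
      paste0(ce$covariate, "->", ce$parameter, " (", ce$form, ")"),
      character(1)), collapse = ", ")
  cat("pk_model_spec: ", x$n_compartments, "-compartment ", x$route,
      if (x$lag) " + lag" else "", "\n",
      "  covariates: ", cov_txt, "\n",
      "  BSV: ", paste(x$bsv, collapse = ", "),
      if (length(x$bov)) paste0("; BOV: ", paste(x$bov, collapse = ", ")) else "",
      "\n  RUV: ", x$ruv, "  (NEP = ", nep(x), ")\n", sep = "")
  invisible(x)
}

#' Parameter bookkeeping for a model spec
#'
#' `param_counts()` returns the number of estimated fixed effects (theta),
#' random-effect variances (omega) and residual variances (sigma);
#' `nep()` is their sum — the parsimony objective of the multi-objective
#' search.
#'
#' @param spec a [pk_model_spec()].
#' @return `param_counts()`: list with `n_theta`, `n_omega`, `n_sigma`;
#'   `nep()`: integer.
#' @export
param_counts <- function(spec) {
  sp <- structural_parameter_names(spec$n_compartments, spec$route, spec$lag)
  list(n_theta = length(sp) + length(spec$covariate_effects),
       n_omega = length(spec$bsv) + length(spec$bov),
       n_sigma = if (spec$ruv == "combined") 2L else 1L)
}

#' @rdname param_counts
#' @export
nep <- function(spec) {
  pc <- param_counts(spec)
  pc$n_theta + pc$n_omega + pc$n_sigma
}

#' Construct a parameter vector
#'
#' @param theta named fixed effects: structural parameters on the natural
#'   scale (positive) plus covariate-effect coefficients named
#'   `"parameter~covariate"`.
#' @param omega named BSV/BOV variances (`"BSV_CL"`, `"BOV_V"`, ...).
#' @param sigma named residual variance components (`"prop"`, `"add"`).
#' @return an object of class `pk_parameters`.
#' @export
pk_parameters <- function(theta, omega = numeric(), sigma) {
  if (any(omega < 0) || any(sigma < 0))
    stop("omega and sigma must be non-negative variances")
  structure(list(theta = theta, omega = omega, sigma = sigma),
            class = "pk_parameters")
}

covariate_theta_name <- function(ce) paste0(ce$parameter, "~", ce$covariate)

parameter_names <- function(spec) {
  sp <- structural_parameter_names(spec$n_compartments, spec$route, spec$lag)
  list(
    theta = c(sp, vapply(spec$covariate_effects, covariate_theta_name,
                         character(1))),
    struct = sp,
    omega = c(if (length(spec$bsv)) paste0("BSV_", spec$bsv),
              if (length(spec$bov)) paste0("BOV_", spec$bov)),
    sigma = switch(spec$ruv, additive = "add", proportional = "prop",
                   combined = c("prop", "add"))
  )
}

## ---- structural predictions ----------------------------------------------

# General linear compartment system via eigendecomposition of the rate
# matrix (the matrix exponential), with dose superposition.  Compartment
# order: [depot (oral only), central, periph2, periph3].
predict_linear_system <- function(spec, p, doses, times) {
  oral <- spec$route == "oral_first_order"
  ncmt <- spec$n_compartments
  dim_ <- ncmt + as.integer(oral)
  cen <- 1L + as.integer(oral)
  A <- matrix(0, dim_, dim_)
  k10 <- p[["CL"]] / p[["V"]]
  A[cen, cen] <- -k10
  if (oral) {
    A[1, 1] <- -p[["KA"]]
    A[cen, 1] <- p[["KA"]]
  }
  if (ncmt >= 2L) {
    k12 <- p[["Q2"]] / p[["V"]]; k21 <- p[["Q2"]] / p[["V2"]]
    i2 <- cen + 1L
    A[cen, cen] <- A[cen, cen] - k12
    A[i2, cen] <- k12; A[cen, i2] <- k21; A[i2, i2] <- -k21
  }
  if (ncmt == 3L) {
    k13 <- p[["Q3"]] / p[["V"]]; k31 <- p[["Q3"]] / p[["V3"]]
    i3 <- cen + 2L
    A[cen, cen] <- A[cen, cen] - k13
    A[i3, cen] <- k13; A[cen, i3] <- k31; A[i3, i3] <- -k31
  }
  eg <- eigen(A)
  if (Mod(rcond_complex(eg$vectors)) < 1e-12) {
    # near-defective rate matrix (e.g. KA coinciding with an elimination
    # eigenvalue): nudge absorption and retry
    p[["KA"]] <- p[["KA"]] * (1 + 1e-7)
    return(predict_linear_system(spec, p, doses, times))
  }
  Pm <- eg$vectors
  Pinv <- solve(Pm)
  dose_cmt <- 1L
  lagt <- if (spec$lag) p[["ALAG"]] else 0
  conc <- numeric(length(times))
  w0 <- Pinv[, dose_cmt]
  for (d in seq_len(nrow(doses))) {
    t0 <- doses$time[d] + if (oral) lagt else 0
    dt <- times - t0
    on <- dt >= 0
    if (!any(on)) next
    E <- exp(outer(eg$values, dt[on]))        # dim_ x n
    amt_cen <- Re(Pm[cen, , drop = FALSE] %*% (E * w0))
    conc[on] <- conc[on] + doses$amt[d] * as.numeric(amt_cen)
  }
  conc / p[["V"]]
}

rcond_complex <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (min(s) == 0) 0 else min(s) / max(s)
}

# Closed-form 1-compartment predictions (fast path used inside estimation).
predict_one_cpt <- function(spec, p, doses, times) {
  ke <- p[["CL"]] / p[["V"]]
  d_time <- doses$time
  d_amt <- doses$amt
  conc <- numeric(length(times))
  if (spec$route == "iv_bolus") {
    for (d in seq_along(d_time)) {
      dt <- times - d_time[d]
      on <- dt >= 0
      conc[on] <- conc[on] + d_amt[d] / p[["V"]] * exp(-ke * dt[on])
    }
  } else {
    ka <- p[["KA"]]
    lagt <- if (spec$lag) p[["ALAG"]] else 0
    for (d in seq_along(d_time)) {
      dt <- times - d_time[d] - lagt
      on <- dt >= 0
      if (!any(on)) next
      tt <- dt[on]
      if (abs(ka - ke) > 1e-8 * max(ka, ke)) {
        conc[on] <- conc[on] + d_amt[d] * ka / (p[["V"]] * (ka - ke)) *
          (exp(-ke * tt) - exp(-ka * tt))
      } else {
        conc[on] <- conc[on] + d_amt[d] * ke * tt * exp(-ke * tt) / p[["V"]]
      }
    }
  }
  conc
}

#' Predict concentrations for one individual
#'
#' Computes concentrations of the linear compartment system for an
#' individual parameter set and dose history, by superposition of unit dose
#' responses.  One-compartment models use the closed forms (IV
#' mono-exponential, oral Bateman); two- and three-compartment models use the
#' eigendecomposition of the rate matrix (the matrix exponential).  An
#' absorption lag shifts the oral input by `ALAG`.
#'
#' @param spec a [pk_model_spec()].
#' @param params_ind named numeric individual parameters on the natural
#'   scale (`CL`, `V`, `Q2`, `V2`, `Q3`, `V3`, `KA`, `ALAG` as applicable).
#' @param doses data frame with columns `time`, `amt`.
#' @param times numeric vector of observation times (>= 0).
#' @return numeric vector of concentrations.
#' @export
predict_conc <- function(spec, params_ind, doses, times) {
  if (params_ind[["CL"]] <= 0 || params_ind[["V"]] <= 0)
    stop("CL and V must be positive")
  if (spec$n_compartments == 1L)
    predict_one_cpt(spec, params_ind, doses, times)
  else
    predict_linear_system(spec, params_ind, doses, times)
}

## ---- covariate & random-effect models ------------------------------------

covariate_factor <- function(form, theta, cov, ref) {
  switch(form,
         power = (cov / ref)^theta,
         linear = 1 + theta * (cov - ref),
         exponential = exp(theta * (cov - ref)),
         proportional_shift = 1 + theta * cov,
         stop("unknown covariate form ", form))
}

#' Reference values for covariate centering
#'
#' Continuous covariates (power/linear/exponential forms) are centered at the
#' dataset median of per-subject values; discrete covariates
#' (proportional-shift form) are referenced at 0.
#'
#' @param spec a [pk_model_spec()].
#' @param dataset a PK dataset (see [read_pk_dataset()]).
#' @return named numeric vector of reference values.
#' @export
covariate_refs <- function(spec, dataset) {
  refs <- numeric(0)
  for (ce in spec$covariate_effects) {
    if (!ce$covariate %in% names(dataset))
      stop("covariate ", ce$covariate, " absent from dataset")
    if (ce$form == "proportional_shift") {
      refs[ce$covariate] <- 0
    } else {
      per_id <- tapply(dataset[[ce$covariate]], dataset$ID, `[`, 1L)
      refs[ce$covariate] <- stats::median(per_id)
    }
  }
  refs
}

# Individual structural parameters: population theta scaled by covariate
# factors, times exp(eta) for BSV parameters and exp(kappa) for BOV
# parameters (kappa is the deviate of the observation's occasion).
individual_params <- function(spec, theta, covs, refs,
                              eta = NULL, kappa = NULL) {
  sp <- structural_parameter_names(spec$n_compartments, spec$route, spec$lag)
  p <- theta[sp]
  for (ce in spec$covariate_effects) {
    th <- theta[[covariate_theta_name(ce)]]
    p[ce$parameter] <- p[ce$parameter] *
      covariate_factor(ce$form, th, covs[[ce$covariate]], refs[[ce$covariate]])
  }
  if (!is.null(eta)) for (nm in names(eta)) p[nm] <- p[nm] * exp(eta[[nm]])
  if (!is.null(kappa)) for (nm in names(kappa)) p[nm] <- p[nm] * exp(kappa[[nm]])
  p
}

## ---- dataset handling ----------------------------------------------------

#' Read / write NONMEM-style PK datasets
#'
#' Expected columns: `ID`, `TIME`, `AMT`, `EVID`, `MDV`, `DV`, optionally
#' `OCC` for occasions, then covariate columns.  `'.'` in `DV` is read as
#' missing.  Column names can be remapped via `col_map` (a named character
#' vector `c(ID = "SUBJ", ...)`).
#'
#' @param path CSV file path.
#' @param col_map optional named remapping of standard column names.
#' @return data frame with standard columns.
#' @export
read_pk_dataset <- function(path, col_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", "."))
  if (!is.null(col_map))
    for (std in names(col_map)) names(d)[names(d) == col_map[[std]]] <- std
  need <- c("ID", "TIME", "AMT", "EVID", "MDV", "DV")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dataset missing required columns: ", paste(miss, collapse = ", "))
  d$DV <- as.numeric(d$DV)
  validate_pk_dataset(d)
  d
}

#' @rdname read_pk_dataset
#' @param dataset data frame of the standard shape.
#' @export
write_pk_dataset <- function(dataset, path) {
  d <- dataset
  d$DV <- ifelse(is.na(d$DV), ".", format(d$DV, digits = 15, trim = TRUE,
                                          scientific = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_pk_dataset <- function(d) {
  for (id in unique(d$ID)) {
    tt <- d$TIME[d$ID == id]
    if (is.unsorted(tt)) stop("TIME must be non-decreasing within subject ", id)
  }
  if (any(d$EVID == 1 & d$MDV != 1))
    stop("dose rows (EVID=1) must have MDV=1")
  invisible(TRUE)
}

# Per-subject estimation structures, built once per fit.
prepare_subjects <- function(spec, dataset) {
  cov_names <- unique(vapply(spec$covariate_effects, `[[`, character(1),
                             "covariate"))
  has_occ <- "OCC" %in% names(dataset)
  if (length(spec$bov) && !has_occ)
    stop("BOV terms require an OCC column in the dataset")
  lapply(split(dataset, dataset$ID), function(d) {
    obs <- d$EVID == 0 & d$MDV == 0 & !is.na(d$DV)
    dose <- d$EVID == 1
    list(id = d$ID[1],
         y = d$DV[obs], times = d$TIME[obs],
         occ = if (has_occ) d$OCC[obs] else rep(1L, sum(obs)),
         occasions = if (has_occ) sort(unique(d$OCC)) else 1L,
         doses = data.frame(time = d$TIME[dose], amt = d$AMT[dose]),
         covs = as.list(d[1, cov_names, drop = FALSE]))
  })
}

## ---- likelihood (FOCE-I / FO) --------------------------------------------

ruv_variance <- function(spec, sigma, f) {
  switch(spec$ruv,
         additive = rep(sigma[["add"]], length(f)),
         proportional = sigma[["prop"]] * f^2,
         combined = sigma[["add"]] + sigma[["prop"]] * f^2)
}

# Random-effect layout for a subject: BSV etas plus one BOV kappa per
# (parameter, occasion).  Returns names, the matching omega variances, and a
# function mapping the packed eta vector to (eta, kappa-by-occasion).
subject_re_layout <- function(spec, omega, occasions) {
  nm <- character(0); var <- numeric(0)
  for (p in spec$bsv) { nm <- c(nm, paste0("BSV_", p)); var <- c(var, omega[[paste0("BSV_", p)]]) }
  for (p in spec$bov) for (oc in occasions) {
    nm <- c(nm, paste0("BOV_", p, "_", oc)); var <- c(var, omega[[paste0("BOV_", p)]])
  }
  list(names = nm, var = var)
}

# Prediction function of the packed random-effect vector for one subject.
# The covariate-scaled base parameters depend on theta and the covariates
# only, so they are assembled once per closure; each call just applies the
# random-effect exponentials and predicts.
subject_ffun <- function(spec, theta, refs, sub) {
  n_bsv <- length(spec$bsv)
  base <- tryCatch(individual_params(spec, theta, sub$covs, refs),
                   error = function(e) NULL)
  if (is.null(base) || any(!is.finite(base)))
    return(function(re) NULL)
  bsv_idx <- match(spec$bsv, names(base))
  bov_idx <- match(spec$bov, names(base))
  clv_idx <- match(c("CL", "V"), names(base))
  function(re) {
    p <- base
    if (n_bsv) p[bsv_idx] <- p[bsv_idx] * exp(re[seq_len(n_bsv)])
    if (length(spec$bov)) {
      f <- numeric(length(sub$times))
      for (oc_pos in seq_along(sub$occasions)) {
        rows <- sub$occ == sub$occasions[oc_pos]
        if (!any(rows)) next
        kap <- re[n_bsv + (seq_along(spec$bov) - 1L) *
                    length(sub$occasions) + oc_pos]
        p_occ <- p
        p_occ[bov_idx] <- p_occ[bov_idx] * exp(kap)
        if (any(!is.finite(p_occ)) || any(p_occ[clv_idx] <= 0)) return(NULL)
        f[rows] <- predict_conc(spec, p_occ, sub$doses, sub$times[rows])
      }
    } else {
      if (any(!is.finite(p)) || any(p[clv_idx] <= 0)) return(NULL)
      f <- predict_conc(spec, p, sub$doses, sub$times)
    }
    f
  }
}

fd_jacobian <- function(ffun, re, f0) {
  n <- length(re)
  G <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- 1e-5 * max(1, abs(re[j]))
    rp <- re; rp[j] <- rp[j] + h
    fp <- ffun(rp)
    if (is.null(fp)) return(NULL)
    G[, j] <- (fp - f0) / h
  }
  G
}

# Empirical-Bayes mode by damped Gauss-Newton on the penalized linearized
# objective (interaction: residual variance at the current individual
# prediction).
eb_mode <- function(spec, sigma, ffun, y, omega_var, re0,
                    max_iter = 20L, tol = 1e-7) {
  re <- re0
  f <- ffun(re)
  if (is.null(f)) { re <- 0 * re; f <- ffun(re) }
  if (is.null(f)) return(NULL)
  obj <- function(re, f) {
    if (any(!is.finite(f))) return(Inf)
    R <- ruv_variance(spec, sigma, f)
    if (any(!is.finite(R)) || any(R <= 0)) return(Inf)
    sum(log(R) + (y - f)^2 / R) + sum(re^2 / omega_var)
  }
  if (any(!is.finite(f))) return(NULL)
  g0 <- obj(re, f)
  for (it in seq_len(max_iter)) {
    G <- fd_jacobian(ffun, re, f)
    if (is.null(G) || any(!is.finite(G))) return(NULL)
    R <- ruv_variance(spec, sigma, f)
    if (any(!is.finite(R)) || any(R <= 0)) return(NULL)
    W <- 1 / R
    A <- crossprod(G, G * W) + diag(1 / omega_var, length(re))
    b <- crossprod(G, W * (y - f + as.numeric(G %*% re)))
    re_new <- tryCatch(as.numeric(solve(A, b)), error = function(e) NULL)
    if (is.null(re_new)) return(NULL)
    step <- re_new - re
    lam <- 1
    repeat {
      cand <- re + lam * step
      fc <- ffun(cand)
      gc <- if (is.null(fc)) Inf else obj(cand, fc)
      if (gc <= g0 + 1e-12 || lam < 1e-3) break
      lam <- lam / 2
    }
    if (!is.finite(gc) || gc > g0) break
    moved <- max(abs(lam * step))
    re <- cand; f <- fc; g0 <- gc
    if (moved < tol) break
  }
  list(re = re, f = f)
}

# `ffun` may be overridden with any prediction function of the packed
# random-effect vector (used to validate the conditional-likelihood chain
# against models whose marginal likelihood has a closed form).
subject_neg2ll <- function(spec, theta, omega, sigma, refs, sub,
                           method = "foce_i", re_start = NULL, ffun = NULL) {
  ffun <- ffun %||% subject_ffun(spec, theta, refs, sub)
  lay <- subject_re_layout(spec, omega, sub$occasions)
  y <- sub$y
  if (length(lay$names) == 0L) {
    f <- ffun(numeric(0))
    if (is.null(f) || any(!is.finite(f))) return(list(val = Inf))
    R <- ruv_variance(spec, sigma, f)
    if (any(!is.finite(R)) || any(R <= 0)) return(list(val = Inf))
    return(list(val = sum(log(R) + (y - f)^2 / R), re = numeric(0)))
  }
  if (any(lay$var <= 0)) return(list(val = Inf))
  re0 <- if (!is.null(re_start) && length(re_start) == length(lay$names))
    re_start else numeric(length(lay$names))
  if (method == "fo") {
    re <- numeric(length(lay$names))
    f <- ffun(re)
    if (is.null(f) || any(!is.finite(f))) return(list(val = Inf))
    mode <- list(re = re, f = f)
  } else {
    mode <- eb_mode(spec, sigma, ffun, y, lay$var, re0)
    if (is.null(mode)) return(list(val = Inf))
  }
  G <- fd_jacobian(ffun, mode$re, mode$f)
  if (is.null(G) || any(!is.finite(G))) return(list(val = Inf))
  R <- ruv_variance(spec, sigma, mode$f)
  if (any(!is.finite(R)) || any(R <= 0)) return(list(val = Inf))
  V <- G %*% (t(G) * lay$var) + diag(R, length(y))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(val = Inf))
  r <- y - mode$f + as.numeric(G %*% mode$re)
  z <- backsolve(ch, r, transpose = TRUE)
  list(val = 2 * sum(log(diag(ch))) + sum(z^2), re = mode$re)
}

#' Approximate -2 log marginal likelihood (OFV)
#'
#' First-order conditional estimation with interaction (FOCE-I): the model is
#' linearized about each subject's empirical-Bayes random-effect mode, with
#' residual variance evaluated at the individual prediction.  The per-subject
#' contribution is `log|V_i| + r_i' V_i^{-1} r_i` with
#' `V_i = G Omega G' + R(f_i)` and `r_i = y_i - f_i + G eta_i`; the additive
#' `n log 2*pi` constant is omitted, matching the convention of standard
#' popPK estimation software (only OFV differences matter to the search).
#' `method = "fo"` linearizes about `eta = 0` instead.
#'
#' Numerical failures (singular `V_i`, non-positive parameters) yield `Inf`
#' rather than an error.
#'
#' @param spec a [pk_model_spec()].
#' @param params a [pk_parameters()].
#' @param dataset PK dataset with at least one observation per subject.
#' @param method `"foce_i"` (default) or `"fo"`.
#' @return the OFV (numeric scalar, `Inf` on numerical failure).
#' @export
neg2loglik <- function(spec, params, dataset, method = c("foce_i", "fo")) {
  method <- match.arg(method)
  refs <- covariate_refs(spec, dataset)
  subs <- prepare_subjects(spec, dataset)
  total <- 0
  for (sub in subs) {
    contrib <- subject_neg2ll(spec, params$theta, params$omega, params$sigma,
                              refs, sub, method)
    if (!is.finite(contrib$val)) return(Inf)
    total <- total + contrib$val
  }
  total
}

## ---- fitting --------------------------------------------------------------

pack_params <- function(spec, params) {
  nm <- parameter_names(spec)
  c(log(params$theta[nm$struct]),
    params$theta[setdiff(nm$theta, nm$struct)],
    log(params$omega[nm$omega]),
    log(params$sigma[nm$sigma]))
}

unpack_params <- function(spec, x) {
  nm <- parameter_names(spec)
  ns <- length(nm$struct)
  nc <- length(nm$theta) - ns
  no <- length(nm$omega)
  nsg <- length(nm$sigma)
  theta <- c(exp(x[seq_len(ns)]),
             if (nc) x[ns + seq_len(nc)] else numeric(0))
  names(theta) <- nm$theta
  omega <- stats::setNames(exp(x[ns + nc + seq_len(no)]), nm$omega)
  sigma <- stats::setNames(exp(x[ns + nc + no + seq_len(nsg)]), nm$sigma)
  pk_parameters(theta, omega, sigma)
}

#' Default starting values for a model spec
#'
#' Crude data-driven heuristics: `V` from dose over peak concentration,
#' `CL` as a tenth of `V` per hour, `KA = 1/h`, peripheral volumes equal to
#' `V` and inter-compartmental clearances equal to `CL`; covariate
#' coefficients start at 0.1, variances at 0.1 (and additive variance at a
#' tenth of the observation variance).
#'
#' @param spec a [pk_model_spec()].
#' @param dataset PK dataset.
#' @return a [pk_parameters()].
#' @export
default_start_values <- function(spec, dataset) {
  obs <- dataset$EVID == 0 & dataset$MDV == 0 & !is.na(dataset$DV)
  dmax <- max(dataset$AMT[dataset$EVID == 1], na.rm = TRUE)
  cmax <- max(dataset$DV[obs], na.rm = TRUE)
  V0 <- max(dmax / max(cmax, 1e-6), 1e-3)
  nm <- parameter_names(spec)
  theta <- stats::setNames(numeric(length(nm$theta)), nm$theta)
  theta["V"] <- V0
  theta["CL"] <- 0.1 * V0
  for (p in c("V2", "V3")) if (p %in% nm$struct) theta[p] <- V0
  for (p in c("Q2", "Q3")) if (p %in% nm$struct) theta[p] <- 0.1 * V0
  if ("KA" %in% nm$struct) theta["KA"] <- 1
  if ("ALAG" %in% nm$struct) theta["ALAG"] <- 0.25
  theta[setdiff(nm$theta, nm$struct)] <- 0.1
  omega <- stats::setNames(rep(0.1, length(nm$omega)), nm$omega)
  sigma <- stats::setNames(rep(0.1, length(nm$sigma)), nm$sigma)
  if ("add" %in% nm$sigma)
    sigma["add"] <- 0.1 * stats::var(dataset$DV[obs]) + 1e-6
  pk_parameters(theta, omega, sigma)
}

# Small deterministic linear congruential generator; keeps the restart
# jitter off R's global RNG stream so evaluations are order-independent.
lcg_runif <- function(seed, n) {
  s <- as.double(seed %% 2147483647)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (16807 * s) %% 2147483647
    out[i] <- s / 2147483647
  }
  out
}

fd_hessian <- function(fn, x, f0, rel_step = 1e-4) {
  n <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(NA_real_, n, n)
  fp <- numeric(n); fm <- numeric(n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    fp[i] <- fn(xp); fm[i] <- fn(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
    xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
    H[i, j] <- H[j, i] <-
      (fn(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fn(xmm)) /
      (2 * h[i] * h[j])
  }
  H
}

#' Fit a candidate model by approximate maximum likelihood
#'
#' Minimizes [neg2loglik()] over `(theta, omega, sigma)` with
#' positive-constrained components on the log scale, using a quasi-Newton
#' optimizer (`nlminb`).  On apparent non-convergence, up to two restarts
#' from deterministically jittered starting values are attempted (the jitter
#' stream is derived from `rng_seed` and never touches R's global RNG, so
#' fits are reproducible and order-independent).  The covariance of the
#' estimates comes from the inverse of a central finite-difference Hessian;
#' from it the correlation matrix, condition number (eigenvalue ratio of the
#' correlation matrix) and per-parameter relative standard errors are
#' derived.  Optimizer failure never raises an error: the result carries
#' `converged = FALSE` and the best OFV found.
#'
#' @param spec a [pk_model_spec()].
#' @param dataset PK dataset.
#' @param method `"foce_i"` or `"fo"`.
#' @param start_values optional [pk_parameters()]; defaults to
#'   [default_start_values()].
#' @param rng_seed integer seed for the deterministic restart jitter.
#' @param max_restarts restarts attempted on non-convergence.
#' @param covariance run the covariance step (finite-difference Hessian).
#'   Skipping it (as estimation tools allow) saves roughly half the cost of
#'   a fit when diagnostics are not needed; the result then has
#'   `covariance_ok = FALSE` and no correlation/condition diagnostics.
#' @return an object of class `pk_fit`: list with `estimates`
#'   ([pk_parameters()]), `ofv`, `converged`, `covariance_ok`,
#'   `correlation_matrix`, `condition_number`, `rse` (%), `n_eval`.
#' @export
fit <- function(spec, dataset, method = c("foce_i", "fo"),
                start_values = NULL, rng_seed = 1L, max_restarts = 2L,
                covariance = TRUE) {
  method <- match.arg(method)
  refs <- covariate_refs(spec, dataset)
  subs <- prepare_subjects(spec, dataset)
  n_eval <- 0L
  # empirical-Bayes modes are re-solved from eta = 0 at every objective
  # evaluation: the objective must be a pure function of the parameters or
  # finite-difference gradients and Hessians become inconsistent
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    par <- tryCatch(unpack_params(spec, x), error = function(e) NULL)
    if (is.null(par)) return(1e10)
    total <- 0
    for (k in seq_along(subs)) {
      contrib <- subject_neg2ll(spec, par$theta, par$omega, par$sigma, refs,
                                subs[[k]], method)
      if (!is.finite(contrib$val)) return(1e10)
      total <- total + contrib$val
    }
    total
  }
  start <- start_values %||% default_start_values(spec, dataset)
  x0_base <- pack_params(spec, start)
  jit <- lcg_runif(rng_seed, max_restarts * length(x0_base))
  best <- NULL
  for (attempt in 0:max_restarts) {
    x0 <- if (attempt == 0) x0_base else
      x0_base + 0.5 * (2 * jit[(attempt - 1) * length(x0_base) +
                                 seq_along(x0_base)] - 1)
    opt <- tryCatch(
      stats::nlminb(x0, objective,
                    control = list(iter.max = 300, eval.max = 600)),
      error = function(e) NULL)
    if (is.null(opt)) next
    conv <- opt$convergence == 0 && is.finite(opt$objective) &&
      opt$objective < 1e9
    if (is.null(best) || opt$objective < best$objective - 1e-9) {
      best <- opt
      best$converged <- conv
    }
    if (conv) break
  }
  if (is.null(best)) {
    np <- length(x0_base)
    return(structure(list(estimates = start, ofv = Inf, converged = FALSE,
                          covariance_ok = FALSE,
                          correlation_matrix = matrix(NA_real_, np, np),
                          condition_number = Inf,
                          rse = rep(NA_real_, np), n_eval = n_eval),
                     class = "pk_fit"))
  }
  est <- unpack_params(spec, best$par)
  ofv <- best$objective
  # covariance step
  H <- if (covariance)
    tryCatch(fd_hessian(objective, best$par, ofv), error = function(e) NULL)
  else NULL
  covariance_ok <- FALSE
  np <- length(best$par)
  corr <- matrix(NA_real_, np, np)
  cond <- Inf
  rse <- rep(NA_real_, np)
  if (!is.null(H) && all(is.finite(H))) {
    ev <- tryCatch(eigen(0.5 * (H + t(H)), symmetric = TRUE,
                         only.values = TRUE)$values, error = function(e) NULL)
    if (!is.null(ev) && all(ev > 1e-10)) {
      covariance_ok <- TRUE
      covm <- 2 * solve(0.5 * (H + t(H)))    # objective is -2 log L
      se_t <- sqrt(pmax(diag(covm), 0))
      corr <- covm / tcrossprod(se_t)
      diag(corr) <- 1
      cond <- condition_number(corr)
      # RSE on the natural scale: log-parameters have RSE ~ 100*SE(log);
      # unconstrained coefficients use 100*SE/|estimate|
      nm <- parameter_names(spec)
      ns <- length(nm$struct); nc <- length(nm$theta) - ns
      is_log <- c(rep(TRUE, ns), rep(FALSE, nc),
                  rep(TRUE, length(nm$omega) + length(nm$sigma)))
      nat <- c(est$theta, est$omega, est$sigma)
      rse <- ifelse(is_log, 100 * se_t,
                    100 * se_t / pmax(abs(c(est$theta, est$omega,
                                            est$sigma)), 1e-12))
      names(rse) <- names(nat)
      dimnames(corr) <- list(names(nat), names(nat))
    }
  }
  structure(list(estimates = est, ofv = ofv,
                 converged = isTRUE(best$converged),
                 covariance_ok = covariance_ok,
                 correlation_matrix = corr,
                 condition_number = cond,
                 rse = rse, n_eval = n_eval),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("pk_fit: OFV =", format(x$ofv, digits = 8),
      "| converged:", x$converged,
      "| covariance:", x$covariance_ok, "\n")
  if (x$covariance_ok)
    cat("  condition number:", format(x$condition_number, digits = 4), "\n")
  est <- c(x$estimates$theta, x$estimates$omega, x$estimates$sigma)
  print(data.frame(estimate = est, rse_pct = round(x$rse[names(est)], 1)))
  invisible(x)
}

## ---- diagnostics ----------------------------------------------------------

#' Condition number of an estimation correlation matrix
#'
#' Ratio of the largest to the smallest eigenvalue.  Values above 1000
#' conventionally signal ill-conditioning of the estimates.
#'
#' @param correlation_matrix symmetric matrix with unit diagonal.
#' @return positive real (>= 1 for a valid correlation matrix; `Inf` when
#'   the smallest eigenvalue is non-positive).
#' @export
condition_number <- function(correlation_matrix) {
  if (!is.matrix(correlation_matrix) ||
      !isSymmetric(unname(correlation_matrix), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  ev <- eigen(correlation_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

#' High-correlation flag for estimation diagnostics
#'
#' Flags a fit when any absolute off-diagonal element of the estimation
#' correlation matrix strictly exceeds the threshold (default 0.95).
#'
#' @param correlation_matrix symmetric correlation matrix.
#' @param threshold strict exceedance threshold.
#' @return logical flag.
#' @export
correlation_flag <- function(correlation_matrix, threshold = 0.95) {
  off <- correlation_matrix
  diag(off) <- 0
  any(abs(off) > threshold, na.rm = TRUE)
}
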