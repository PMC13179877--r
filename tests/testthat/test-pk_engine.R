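test_that("model specs validate structure and count parameters", {
  spec <- pk_model_spec(2L, "oral_first_order", lag = TRUE,
                        covariate_effects = list(
                          list(parameter = "CL", covariate = "WT",
                               form = "power")),
                        bsv = c("CL", "V"), ruv = "combined")
  pc <- param_counts(spec)
  # CL V Q2 V2 KA ALAG + 1 covariate theta; 2 omegas; 2 sigmas
  expect_equal(pc, list(n_theta = 7L, n_omega = 2L, n_sigma = 2L))
  expect_equal(nep(spec), 11L)
  expect_error(pk_model_spec(1L, "iv_bolus", lag = TRUE), "oral")
  expect_error(pk_model_spec(1L, bsv = "Q2"), "absent")
})

test_that("IV bolus prediction starts at dose over volume", {
  spec <- pk_model_spec(1L, "iv_bolus")
  conc <- predict_conc(spec, c(CL = 5, V = 50),
                       data.frame(time = 0, amt = 100), c(0, 1))
  expect_equal(conc[1], 100 / 50)
  expect_error(predict_conc(spec, c(CL = -1, V = 50),
                            data.frame(time = 0, amt = 100), 0), "positive")
})

test_that("oral predictions equal the Bateman closed form", {
  spec <- pk_model_spec(1L, "oral_first_order")
  p <- c(CL = 4, V = 35, KA = 1.7)
  ke <- p[["CL"]] / p[["V"]]
  set.seed(71)
  tt <- sort(runif(10, 0.1, 48))
  f <- predict_conc(spec, p, data.frame(time = 0, amt = 100), tt)
  bate <- 100 * p[["KA"]] / (p[["V"]] * (p[["KA"]] - ke)) *
    (exp(-ke * tt) - exp(-p[["KA"]] * tt))
  expect_equal(f, bate, tolerance = 1e-12)
})

test_that("linear kinetics superpose across doses", {
  for (route in c("iv_bolus", "oral_first_order")) {
    spec <- pk_model_spec(2L, route)
    p <- c(CL = 5, V = 50, Q2 = 10, V2 = 80, KA = 1.1)
    tt <- c(1, 6, 13, 20, 30)
    two <- predict_conc(spec, p, data.frame(time = c(0, 12), amt = 100), tt)
    one_a <- predict_conc(spec, p, data.frame(time = 0, amt = 100), tt)
    one_b <- predict_conc(spec, p, data.frame(time = 12, amt = 100), tt)
    expect_equal(two, one_a + one_b, tolerance = 1e-10)
  }
})

test_that("matrix-exponential engine matches hand-coded closed forms", {
  set.seed(81)
  tt <- sort(runif(12, 0.05, 36))
  for (i in 1:100) {
    CL <- runif(1, 1, 20); V <- runif(1, 10, 200)
    if (i %% 2 == 0) {
      # 1-compartment oral: Bateman function
      KA <- runif(1, 0.3, 3)
      spec <- pk_model_spec(1L, "oral_first_order")
      p <- c(CL = CL, V = V, KA = KA)
      ke <- CL / V
      ref <- 100 * KA / (V * (KA - ke)) * (exp(-ke * tt) - exp(-KA * tt))
      got <- pkmoo:::predict_linear_system(spec, p, data.frame(time = 0, amt = 100), tt)
    } else {
      # 2-compartment IV: bi-exponential macro constants
      Q2 <- runif(1, 1, 30); V2 <- runif(1, 20, 300)
      spec <- pk_model_spec(2L, "iv_bolus")
      p <- c(CL = CL, V = V, Q2 = Q2, V2 = V2)
      k10 <- CL / V; k12 <- Q2 / V; k21 <- Q2 / V2
      s <- k10 + k12 + k21
      beta <- 0.5 * (s - sqrt(s^2 - 4 * k10 * k21))
      alpha <- k10 * k21 / beta
      A <- 100 / V * (alpha - k21) / (alpha - beta)
      B <- 100 / V * (k21 - beta) / (alpha - beta)
      ref <- A * exp(-alpha * tt) + B * exp(-beta * tt)
      got <- pkmoo:::predict_linear_system(spec, p, data.frame(time = 0, amt = 100), tt)
    }
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("concentrations decay to zero and stay non-negative", {
  spec <- pk_model_spec(3L, "oral_first_order")
  p <- c(CL = 5, V = 50, Q2 = 10, V2 = 80, Q3 = 2, V3 = 300, KA = 0.9)
  tt <- c(seq(0.5, 48, by = 0.5), 500, 5000)
  f <- predict_conc(spec, p, data.frame(time = 0, amt = 100), tt)
  expect_true(all(f >= 0))
  expect_lt(f[length(f)], 1e-8)
})

test_that("with no random effects the OFV collapses to weighted least squares", {
  spec <- pk_model_spec(1L, "oral_first_order", bsv = character(),
                        ruv = "additive")
  fx <- example_fixture(10L)
  d <- fx$data
  pars <- pk_parameters(c(CL = 5, V = 50, KA = 1.2), numeric(),
                        c(add = 0.04))
  got <- neg2loglik(spec, pars, d)
  obs <- d$EVID == 0 & d$MDV == 0
  f <- unlist(lapply(split(d, d$ID), function(s) {
    o <- s$EVID == 0
    predict_conc(spec, c(CL = 5, V = 50, KA = 1.2),
                 data.frame(time = s$TIME[s$EVID == 1],
                            amt = s$AMT[s$EVID == 1]), s$TIME[o])
  }), use.names = FALSE)
  manual <- sum(log(0.04) + (d$DV[obs] - f)^2 / 0.04)
  expect_equal(got, manual, tolerance = 1e-10)
})

test_that("FOCE chain reproduces the closed-form linear mixed model", {
  # prediction exactly linear in the random effect: f(eta) = theta*(1+eta)*t
  # => y ~ N(theta t, omega (theta t)(theta t)' + sigma^2 I) exactly, and the
  # conditional linearization is exact
  spec <- pk_model_spec(1L, "iv_bolus", bsv = "CL", ruv = "additive")
  theta0 <- 2.5; omega <- c(BSV_CL = 0.3); sigma <- c(add = 0.5)
  tt <- c(1, 2, 4, 7)
  set.seed(91)
  y <- theta0 * (1 + rnorm(1, 0, sqrt(omega))) * tt + rnorm(4, 0, sqrt(sigma))
  sub <- list(id = 1, y = y, times = tt, occ = rep(1L, 4), occasions = 1L,
              doses = data.frame(time = 0, amt = 1), covs = list())
  lin_ffun <- function(re) theta0 * (1 + re[1]) * tt
  got <- pkmoo:::subject_neg2ll(spec, c(CL = theta0, V = 1), omega, sigma,
                                numeric(0), sub, ffun = lin_ffun)$val
  Vm <- omega * tcrossprod(theta0 * tt) + diag(sigma, 4)
  r <- y - theta0 * tt
  manual <- determinant(Vm, logarithm = TRUE)$modulus[1] +
    as.numeric(r %*% solve(Vm, r))
  expect_equal(got, manual, tolerance = 1e-6)
})

test_that("the OFV is lower at generating parameters than when perturbed", {
  spec <- example_scenario()$truth_spec
  true_p <- example_scenario()$truth_params
  pert <- pk_parameters(true_p$theta * 1.5, true_p$omega, true_p$sigma)
  wins <- 0L
  for (s in 1:20) {
    d <- generate_dataset(example_scenario(n_subjects = 10L,
                                           rng_seed = 100 + s))$data
    if (neg2loglik(spec, true_p, d) < neg2loglik(spec, pert, d))
      wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("the OFV is invariant to subject ordering", {
  fx <- example_fixture(10L)
  d <- fx$data
  set.seed(101)
  ids <- sample(unique(d$ID))
  d2 <- do.call(rbind, lapply(ids, function(i) d[d$ID == i, ]))
  pars <- fx$truth$params
  expect_equal(neg2loglik(fx$truth$spec, pars, d),
               neg2loglik(fx$truth$spec, pars, d2), tolerance = 1e-6)
})

test_that("repeated fits with identical seeds are bit-identical", {
  fx <- example_fixture(8L)
  f1 <- fit(fx$truth$spec, fx$data, rng_seed = 3L, covariance = FALSE)
  f2 <- fit(fx$truth$spec, fx$data, rng_seed = 3L, covariance = FALSE)
  expect_identical(f1$ofv, f2$ofv)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("a superset model never fits worse at its optimum", {
  spec1 <- pk_model_spec(1L, "iv_bolus", bsv = "CL", ruv = "proportional")
  params <- pk_parameters(c(CL = 5, V = 50), c(BSV_CL = 0.04),
                          c(prop = 0.01))
  sc <- pk_scenario(spec1, params, n_subjects = 12L, dose_amount = 100,
                    rich_times = c(0.5, 1, 2, 4, 8, 16, 24, 36),
                    rng_seed = 13L)
  d <- generate_dataset(sc)$data
  f1 <- fit(spec1, d, covariance = FALSE)
  spec2 <- pk_model_spec(2L, "iv_bolus", bsv = "CL", ruv = "proportional")
  # start the superset at the subset optimum (tiny peripheral exchange)
  st <- pk_parameters(c(f1$estimates$theta, Q2 = 0.01,
                        V2 = f1$estimates$theta[["V"]]),
                      f1$estimates$omega, f1$estimates$sigma)
  f2 <- fit(spec2, d, start_values = st, covariance = FALSE)
  expect_true(f1$converged)
  expect_lte(f2$ofv, f1$ofv + 1e-6)
})

test_that("condition number is the eigenvalue ratio of the correlation matrix", {
  expect_equal(condition_number(diag(3)), 1)
  m <- matrix(c(1, 0.95, 0.95, 1), 2)
  expect_equal(condition_number(m), (1 + 0.95) / (1 - 0.95), tolerance = 1e-12)
  set.seed(111)
  A <- matrix(rnorm(25), 5)
  S <- crossprod(A) + diag(5)
  R <- stats::cov2cor(S)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(condition_number(R), max(ev) / min(ev))
  expect_error(condition_number(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("the correlation check uses a strict threshold", {
  m <- function(r) matrix(c(1, r, r, 1), 2)
  expect_true(correlation_flag(m(0.96)))
  expect_false(correlation_flag(m(0.95)))   # exactly at the bound passes
  expect_false(correlation_flag(diag(4)))
  expect_true(correlation_flag(m(-0.97)))
})

test_that("datasets round-trip through NONMEM-style CSV", {
  fx <- example_fixture(6L)
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(fx$data, path)
  d2 <- read_pk_dataset(path)
  expect_equal(d2$DV[d2$EVID == 0], fx$data$DV[fx$data$EVID == 0],
               tolerance = 1e-12)
  expect_true(all(is.na(d2$DV[d2$EVID == 1])))
  pars <- fx$truth$params
  expect_equal(neg2loglik(fx$truth$spec, pars, d2),
               neg2loglik(fx$truth$spec, pars, fx$data), tolerance = 1e-9)
})
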