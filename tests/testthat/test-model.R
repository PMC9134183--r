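test_that("prior densities and transforms match closed forms in z-space", {
  pars <- dplyr::bind_rows(
    prior_spec("a", "lognormal", log(10), 1),
    prior_spec("b", "normal", 2, 3),
    prior_spec("c", "halfnormal", 5),
    prior_spec("d", "gamma", 2, 0.5),
    prior_spec("e", "uniform", 1, 100))
  pars$transform <- kinflow:::prior_transform(pars$dist)
  z <- c(1.2, -0.7, 0.4, 0.9, 0.3)
  ev <- kinflow:::prior_eval_z(pars, z)
  # phi(z): exp for log-transformed, identity, scaled logistic for uniform
  expect_equal(ev$phi, c(exp(1.2), -0.7, exp(0.4), exp(0.9),
                         1 + 99 * stats::plogis(0.3)))
  # z-space density = natural density * |d phi / d z|
  expect_equal(ev$lp[1], stats::dlnorm(exp(1.2), log(10), 1, log = TRUE) + 1.2)
  expect_equal(ev$lp[3],
               log(2) + stats::dnorm(exp(0.4), 0, 5, log = TRUE) + 0.4)
  expect_equal(ev$lp[4],
               stats::dgamma(exp(0.9), 2, rate = 0.5, log = TRUE) + 0.9)
  s <- stats::plogis(0.3)
  expect_equal(ev$lp[5], stats::dunif(ev$phi[5], 1, 100, log = TRUE) +
                 log(99 * s * (1 - s)))
  # gradients match finite differences
  for (j in seq_along(z)) {
    f <- function(x) { zz <- z; zz[j] <- x
      kinflow:::prior_eval_z(pars, zz)$lp[j] }
    h <- 1e-6
    expect_equal(ev$dlp[j], (f(z[j] + h) - f(z[j] - h)) / (2 * h),
                 tolerance = 1e-5)
  }
  # round trip phi -> z -> phi
  expect_equal(kinflow:::prior_eval_z(pars, kinflow:::phi_to_z(pars, ev$phi))$phi,
               ev$phi, tolerance = 1e-8)
})

test_that("joint model composes: one observation's log-posterior is prior + one Gaussian term", {
  obs <- tibble::tibble(experiment_id = "e1", topology_id = "mm", k_f = 1,
                        inflow_S = 1, observed_species = "P", value = 0.6,
                        replicate = 1)
  m <- quiet_model(obs)
  expect_equal(nrow(model_parameters(m)), 3)  # kcat, Km, sigma_e1
  z <- kinflow:::prior_median_z(m$pars) + 0.1
  ev <- kinflow:::prior_eval_z(m$pars_plain, z)
  pred <- kinflow:::model_predict(m, ev$phi)
  sig <- ev$phi[m$pars$param == "sigma_e1"]
  expect_equal(log_posterior(m, z, grad = FALSE)$value,
               sum(ev$lp) + stats::dnorm(0.6, pred, sig, log = TRUE))
})

test_that("concatenating disjoint datasets adds their log-likelihoods", {
  sc <- scenario_trypsin(s_in = c(100, 500), replicates = 1)
  obs <- generate_observations(sc, seed = 3)
  o1 <- dplyr::filter(obs, experiment_id == "tryp_no_inh")
  o2 <- dplyr::filter(obs, experiment_id == "tryp_with_inh")
  # fix shared priors so the three models use identical distributions
  pri <- dplyr::bind_rows(
    prior_spec("E_kcat", "lognormal", log(10), 1),
    prior_spec("E_Km_S", "lognormal", log(100), 1),
    prior_spec("E_Ki", "uniform", 1, 1e4),
    prior_spec("sigma_tryp_no_inh", "halfnormal", 20),
    prior_spec("sigma_tryp_with_inh", "halfnormal", 20))
  m12 <- quiet_model(obs, priors = pri)
  m1 <- quiet_model(o1, priors = pri)
  m2 <- quiet_model(o2, priors = pri)
  phi <- c(E_kcat = 25, E_Km_S = 150, E_Ki = 700,
           sigma_tryp_no_inh = 4, sigma_tryp_with_inh = 6)
  ll_of <- function(m) {
    z <- kinflow:::phi_to_z(m$pars, phi[m$pars$param])
    lp <- log_posterior(m, z, grad = FALSE)$value
    pr <- sum(kinflow:::prior_eval_z(m$pars_plain, z)$lp)
    lp - pr
  }
  expect_equal(ll_of(m12), ll_of(m1) + ll_of(m2), tolerance = 1e-10)
})

test_that("likelihood is invariant to a common shift of data and predictions", {
  # Gaussian location family: shifting observed values and the predicted
  # steady state by the same constant leaves each term's density unchanged
  y <- 42; mu <- 40; sig <- 3
  expect_equal(stats::dnorm(y, mu, sig, log = TRUE),
               stats::dnorm(y + 17, mu + 17, sig, log = TRUE))
})

test_that("gradient of the joint posterior matches finite differences (incl. sigma)", {
  sc <- scenario_trypsin(s_in = c(100, 1000), replicates = 2)
  obs <- generate_observations(sc, seed = 4)
  m <- quiet_model(obs)
  z <- kinflow:::prior_median_z(m$pars) + c(0.2, -0.1, 0.4, 0.1, -0.3)
  ev <- log_posterior(m, z)
  fd <- kinflow:::central_diff(function(zz) log_posterior(m, zz, grad = FALSE)$value, z)
  expect_equal(ev$gradient, as.numeric(fd), tolerance = 1e-4)
  # sigma gradient alone matches the closed form -1/s + r^2/s^3 (chain rule
  # through the log transform multiplies by s)
  phi <- kinflow:::prior_eval_z(m$pars_plain, z)$phi
  pred <- kinflow:::model_predict(m, phi)
  i_sig <- which(m$pars$param == "sigma_tryp_no_inh")
  rows <- which(obs$experiment_id == "tryp_no_inh")
  s <- phi[i_sig]
  closed <- sum(-1 / s + (obs$value[rows] - pred[rows])^2 / s^3) * s
  prior_part <- kinflow:::prior_eval_z(m$pars_plain, z)$dlp[i_sig]
  expect_equal(ev$gradient[i_sig], closed + prior_part, tolerance = 1e-8)
})

test_that("orphan parameters are reported and sharing declarations validated", {
  obs <- tibble::tibble(experiment_id = "e1", topology_id = "mm", k_f = 1,
                        inflow_S = 1, observed_species = "P", value = 0.5)
  map <- dplyr::bind_rows(
    default_parameter_map(obs),
    tibble::tibble(topology_id = "mm", enzyme = "E", role = "kcat",
                   param = "unused_param", experiment_id = "ghost_exp"))
  expect_warning(flow_model(obs, parameter_map = map, quiet = TRUE), "unused_param")
  bad_map <- tibble::tibble(topology_id = "mm", enzyme = "E", role = "kcat",
                            param = "E_kcat", experiment_id = NA_character_)
  expect_error(flow_model(obs, parameter_map = bad_map, quiet = TRUE), "Km_S")
})

test_that("observations are validated: species observability and negative values", {
  obs <- tibble::tibble(experiment_id = "e1", topology_id = "gdh_hk", k_f = 1,
                        inflow_Glc = 10, observed_species = "Glc", value = 1)
  expect_error(flow_model(obs, quiet = TRUE), "not observable")
  obs2 <- tibble::tibble(experiment_id = "e1", topology_id = "mm", k_f = 1,
                         inflow_S = 1, observed_species = "P", value = -2)
  expect_error(flow_model(obs2, quiet = TRUE), "row 1")
})

test_that("free inflow conditions enter the posterior with working gradients", {
  sc <- scenario_trypsin(s_in = c(200, 800), replicates = 2)
  obs <- generate_observations(sc, seed = 9)
  fc <- tibble::tibble(experiment_id = "tryp_no_inh", species = "S",
                       param = "S_in_no_inh")
  pri <- prior_spec("S_in_no_inh", "normal", 500, 50)
  m <- quiet_model(obs, free_conditions = fc, priors = pri)
  expect_true("S_in_no_inh" %in% m$pars$param)
  z <- kinflow:::prior_median_z(m$pars) + 0.15
  ev <- log_posterior(m, z)
  fd <- kinflow:::central_diff(function(zz) log_posterior(m, zz, grad = FALSE)$value, z)
  expect_equal(ev$gradient, as.numeric(fd), tolerance = 1e-4)
})

test_that("steady-state failure maps to a rejected (-Inf) proposal", {
  obs <- tibble::tibble(experiment_id = "e1", topology_id = "mm", k_f = 1,
                        inflow_S = 1, observed_species = "P", value = 0.5)
  m <- quiet_model(obs)
  lp <- log_posterior(m, c(1e4, 0, 0), grad = FALSE)  # overflow kcat
  expect_true(lp$value == -Inf || is.finite(lp$value))
  lp2 <- log_posterior(m, c(Inf, 0, 0), grad = FALSE)
  expect_identical(lp2$value, -Inf)
})
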