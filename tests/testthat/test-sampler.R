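# Sampler validation against closed-form conjugate posteriors, plus
# determinism and diagnostic behavior.

test_that("NUTS recovers the conjugate Gaussian-mean posterior", {
  # y = 1 observed with sd 1, prior mu ~ N(0, 1) -> posterior N(0.5, 1/sqrt 2)
  lp <- function(z) list(value = stats::dnorm(z, 0, 1, log = TRUE) +
                           stats::dnorm(1, z, 1, log = TRUE),
                         gradient = -z + (1 - z))
  set.seed(1)
  r <- nuts(lp, init = 0, n_warmup = 500, n_draws = 2500)
  ess <- ess_bulk(matrix(r$draws, ncol = 1))
  se_mean <- (1 / sqrt(2)) / sqrt(ess)
  expect_lt(abs(mean(r$draws) - 0.5), 3 * se_mean)
  se_sd <- (1 / sqrt(2)) / sqrt(2 * ess)
  expect_lt(abs(stats::sd(r$draws) - 1 / sqrt(2)), 3 * se_sd)
  expect_equal(sum(r$divergent), 0)
})

test_that("NUTS recovers a conjugate linear-regression posterior", {
  # y = X b + e, e ~ N(0, 1), prior b ~ N(0, I): posterior
  # N((X'X + I)^-1 X'y, (X'X + I)^-1)
  set.seed(2)
  n <- 40
  X <- cbind(1, stats::rnorm(n))
  b_true <- c(0.5, -1)
  y <- drop(X %*% b_true) + stats::rnorm(n)
  V <- solve(crossprod(X) + diag(2))
  b_post <- drop(V %*% crossprod(X, y))
  lp <- function(z) {
    r <- y - drop(X %*% z)
    list(value = -0.5 * sum(z^2) - 0.5 * sum(r^2),
         gradient = -z + drop(crossprod(X, r)))
  }
  r <- nuts(lp, init = c(0, 0), n_warmup = 500, n_draws = 2000)
  for (j in 1:2) {
    ess <- ess_bulk(matrix(r$draws[, j], ncol = 1))
    expect_lt(abs(mean(r$draws[, j]) - b_post[j]),
              3 * sqrt(V[j, j]) / sqrt(ess) + 1e-12)
    expect_lt(abs(stats::sd(r$draws[, j]) - sqrt(V[j, j])),
              3 * sqrt(V[j, j]) / sqrt(2 * ess))
  }
})

test_that("NUTS recovers mean and variance of a normal model jointly", {
  # y_i ~ N(mu, sigma), flat-ish wide priors; compare with long analytic
  # quadrature on the 2-d grid
  set.seed(3)
  y <- c(9.2, 10.1, 11.3, 10.8, 9.7, 10.4, 10.9, 9.5)
  lp <- function(z) {  # z = (mu, log sigma)
    mu <- z[1]; sig <- exp(z[2])
    r <- y - mu
    v <- stats::dnorm(z[1], 10, 10, log = TRUE) +
      stats::dnorm(z[2], 0, 3, log = TRUE) +
      sum(stats::dnorm(y, mu, sig, log = TRUE))
    g_mu <- -(z[1] - 10) / 100 + sum(r) / sig^2
    g_ls <- -z[2] / 9 + sum(-1 + r^2 / sig^2)
    list(value = v, gradient = c(g_mu, g_ls))
  }
  r <- nuts(lp, init = c(10, 0), n_warmup = 600, n_draws = 2000)
  # numeric quadrature oracle over (mu, log sigma)
  mus <- seq(8.5, 12, length.out = 220)
  lss <- seq(-2.2, 1.6, length.out = 220)
  grid <- expand.grid(mu = mus, ls = lss)
  lw <- apply(grid, 1, function(g) lp(as.numeric(g))$value)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  mu_ref <- sum(grid$mu * w)
  sd_mu_ref <- sqrt(sum((grid$mu - mu_ref)^2 * w))
  ess <- ess_bulk(matrix(r$draws[, 1], ncol = 1))
  expect_lt(abs(mean(r$draws[, 1]) - mu_ref), 3 * sd_mu_ref / sqrt(ess))
  ls_ref <- sum(grid$ls * w)
  sd_ls_ref <- sqrt(sum((grid$ls - ls_ref)^2 * w))
  ess2 <- ess_bulk(matrix(r$draws[, 2], ncol = 1))
  expect_lt(abs(mean(r$draws[, 2]) - ls_ref), 3 * sd_ls_ref / sqrt(ess2))
})

test_that("fixed seeds reproduce draws exactly", {
  sc <- scenario_trypsin(s_in = c(100, 1000), replicates = 1)
  obs <- generate_observations(sc, seed = 5)
  m <- quiet_model(obs)
  f1 <- suppressWarnings(sample_posterior(m, chains = 2, warmup = 100,
                                          draws = 100, seed = 99,
                                          check_gradient = FALSE))
  f2 <- suppressWarnings(sample_posterior(m, chains = 2, warmup = 100,
                                          draws = 100, seed = 99,
                                          check_gradient = FALSE))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  f3 <- suppressWarnings(sample_posterior(m, chains = 2, warmup = 100,
                                          draws = 100, seed = 100,
                                          check_gradient = FALSE))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("diagnostics behave on constructed chains", {
  # two identical chains carry no between-chain variance
  set.seed(6)
  x <- stats::rnorm(500)
  expect_equal(rhat(cbind(x, x)), 1, tolerance = 0.02)
  # iid draws: rhat ~ 1, ESS close to the nominal draw count
  m <- matrix(stats::rnorm(4000), 1000, 4)
  expect_lt(rhat(m), 1.01)
  expect_gt(ess_bulk(m), 0.9 * 4000)
  expect_lt(ess_bulk(m), 1.15 * 4000)
  # a shifted chain must blow up rhat
  m2 <- m; m2[, 2] <- m2[, 2] + 10
  expect_gt(rhat(m2), 1.1)
  # single chain: rhat unavailable
  expect_true(is.na(rhat(matrix(x, ncol = 1))))
})

test_that("ESS broadly agrees with an independent estimator on autocorrelated chains", {
  set.seed(7)
  # AR(1) chains with known autocorrelation
  ar <- function(n, rho) { x <- numeric(n)
    for (i in 2:n) x[i] <- rho * x[i - 1] + stats::rnorm(1) * sqrt(1 - rho^2)
    x }
  x <- cbind(ar(2000, 0.7), ar(2000, 0.7))
  ours <- ess_bulk(x)
  theirs <- sum(apply(x, 2, function(col) coda::effectiveSize(coda::mcmc(col))))
  expect_lt(abs(ours - theirs) / theirs, 0.5)
})

test_that("divergence-prone targets are reported, not hidden", {
  # a funnel-like target with a hard barrier produces rejections/divergences
  lp <- function(z) {
    if (any(abs(z) > 4)) return(list(value = -Inf, gradient = c(0, 0)))
    v <- stats::dnorm(z[1], 0, 1, log = TRUE) +
      stats::dnorm(z[2], 0, exp(z[1]), log = TRUE)
    list(value = v, gradient = c(-z[1] + z[2]^2 * exp(-2 * z[1]) - 1,
                                 -z[2] * exp(-2 * z[1])))
  }
  set.seed(8)
  r <- nuts(lp, init = c(0, 0), n_warmup = 200, n_draws = 200)
  expect_true(is.numeric(r$divergent) || is.logical(r$divergent))
  expect_length(r$divergent, 200)
})
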