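test_that("generalized Pareto fit recovers a known tail shape", {
  set.seed(20)
  rgpd <- function(n, k, s) s * (stats::runif(n)^(-k) - 1) / k
  x <- rgpd(4000, 0.4, 1)
  f <- gpd_fit(x)
  expect_lt(abs(f$k - 0.4), 0.15)
  expect_gt(f$sigma, 0)
  # light-tailed sample gives a clearly smaller shape
  f2 <- gpd_fit(stats::rexp(4000))
  expect_lt(f2$k, 0.2)
})

test_that("PSIS smoothing normalizes, preserves order, and handles degenerate tails", {
  set.seed(21)
  lr <- stats::rnorm(2000, 0, 2)
  ps <- psis_smooth(lr)
  expect_equal(sum(exp(ps$log_weights)), 1, tolerance = 1e-10)
  # smoothing is monotone: weights non-decreasing along the sorted ratios
  expect_true(all(diff(ps$log_weights[order(lr)]) >= -1e-12))
  expect_equal(ps$tail_len, ceiling(min(0.2 * 2000, 3 * sqrt(2000))))
  # constant ratios: uniform weights, shape reported as degenerate-low
  ps0 <- psis_smooth(rep(2.5, 64))
  expect_identical(ps0$khat, -Inf)
  expect_equal(exp(ps0$log_weights), rep(1 / 64, 64))
  # heavy-tailed ratios are flagged by a large khat
  ps_heavy <- psis_smooth(log(1 / stats::runif(2000)^(1.3)))
  expect_gt(ps_heavy$khat, 0.7)
})

test_that("pointwise log-likelihood matrix obeys the Gaussian identities", {
  sc <- scenario_trypsin(s_in = c(100, 1000), replicates = 1)
  obs <- generate_observations(sc, seed = 22)
  m <- quiet_model(obs)
  f <- suppressWarnings(
    sample_posterior(m, chains = 2, warmup = 100, draws = 100, seed = 1,
                     check_gradient = FALSE))
  ll <- pointwise_loglik(f)
  expect_equal(dim(ll), c(200, nrow(obs)))
  # row sums equal the model's total log-likelihood at that draw
  phi <- kinflow:::flat_draws(f)
  for (s in c(1, 57, 200)) {
    pred <- kinflow:::model_predict(m, phi[s, ])
    sig <- phi[s, paste0("sigma_", obs$experiment_id)]
    expect_equal(sum(ll[s, ]),
                 sum(stats::dnorm(obs$value, pred, sig, log = TRUE)))
  }
  # closed-form entries: standardized residual 0 and residual = sigma
  expect_equal(stats::dnorm(0, 0, 1, log = TRUE), -0.5 * log(2 * pi))
  expect_equal(stats::dnorm(3, 0, 3, log = TRUE),
               -0.5 * log(2 * pi) - log(3) - 0.5)
})

test_that("PSIS-LOO matches the closed-form exact LOO on a conjugate model", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1): all leave-one-out predictive densities are
  # closed-form Gaussians, and the posterior can be sampled exactly
  set.seed(23)
  y <- c(0.3, -0.8, 1.2, 0.5, -0.2)
  n <- length(y)
  post_var <- 1 / (n + 1); post_mean <- sum(y) * post_var
  S <- 8000
  mu_draws <- stats::rnorm(S, post_mean, sqrt(post_var))
  ll <- vapply(y, function(yi) stats::dnorm(yi, mu_draws, 1, log = TRUE),
               numeric(S))
  got <- loo_from_loglik(ll)
  exact <- sum(vapply(seq_len(n), function(i) {
    v_i <- 1 / n; m_i <- sum(y[-i]) * v_i
    stats::dnorm(y[i], m_i, sqrt(1 + v_i), log = TRUE)
  }, numeric(1)))
  # Monte-Carlo SE of the PSIS estimate via draw-level jackknife is ~0.01;
  # use the pointwise SE as the (conservative) yardstick
  expect_lt(abs(got$elpd_loo - exact), 3 * max(got$se_elpd / sqrt(n), 0.02))
  expect_true(all(got$pointwise$khat < 0.7))
})

test_that("elpd approximately doubles under dataset duplication", {
  set.seed(24)
  y <- stats::rnorm(10, 1, 1)
  n <- length(y)
  post_var <- 1 / (n + 1); post_mean <- sum(y) * post_var
  mu_draws <- stats::rnorm(4000, post_mean, sqrt(post_var))
  ll1 <- vapply(y, function(yi) stats::dnorm(yi, mu_draws, 1, log = TRUE),
                numeric(4000))
  ll2 <- cbind(ll1, ll1)
  l1 <- loo_from_loglik(ll1); l2 <- loo_from_loglik(ll2)
  expect_lt(abs(l2$elpd_loo - 2 * l1$elpd_loo),
            2 * sqrt(l1$se_elpd^2 + l2$se_elpd^2) + 0.5)
})

test_that("exact refits engage above the khat threshold and agree with PSIS", {
  sc <- scenario_trypsin(s_in = c(100, 400, 1500), replicates = 2)
  obs <- generate_observations(sc, seed = 25)
  m <- quiet_model(obs)
  f <- sample_posterior(m, chains = 2, warmup = 200, draws = 300, seed = 2,
                        check_gradient = FALSE)
  psis_only <- loo_elpd(f, khat_threshold = Inf)
  # forcing refits on the two highest-khat points reproduces the PSIS answer
  ks <- sort(psis_only$pointwise$khat, decreasing = TRUE)
  thr <- mean(ks[2:3])
  with_refits <- loo_elpd(f, khat_threshold = thr)
  expect_equal(with_refits$n_exact, sum(psis_only$pointwise$khat > thr))
  expect_gt(with_refits$n_exact, 0)
  expect_lt(abs(with_refits$elpd_loo - psis_only$elpd_loo),
            3 * psis_only$se_elpd)
})

test_that("model comparison ranks, differences and invariances behave", {
  set.seed(26)
  y <- stats::rnorm(12)
  mu_draws <- stats::rnorm(2000, mean(y), 0.3)
  ll_a <- vapply(y, function(yi) stats::dnorm(yi, mu_draws, 1, log = TRUE),
                 numeric(2000))
  ll_b <- ll_a - 0.4  # uniformly worse predictive density
  la <- loo_from_loglik(ll_a); lb <- loo_from_loglik(ll_b)
  cmp <- compare_models(good = la, bad = lb)
  expect_equal(cmp$model, c("good", "bad"))
  expect_equal(cmp$elpd_diff[1], 0)
  expect_equal(cmp$se_diff[1], 0)
  expect_equal(cmp$elpd_diff[2], -0.4 * 12, tolerance = 1e-6)
  # comparing a model with itself: zero difference, zero SE
  cmp_self <- compare_models(a = la, b = la)
  expect_equal(cmp_self$elpd_diff[2], 0)
  expect_equal(cmp_self$se_diff[2], 0)
  # invariant to observation ordering
  perm <- sample(12)
  la_p <- loo_from_loglik(ll_a[, perm]); lb_p <- loo_from_loglik(ll_b[, perm])
  cmp_p <- compare_models(good = la_p, bad = lb_p)
  expect_equal(cmp_p$elpd_loo, cmp$elpd_loo, tolerance = 1e-10)
  expect_equal(cmp_p$se_diff, cmp$se_diff, tolerance = 1e-10)
  # mismatched observation sets are rejected
  expect_error(compare_models(a = la, b = loo_from_loglik(ll_a[, 1:5])),
               "different numbers")
})
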