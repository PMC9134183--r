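# No-U-Turn sampler with dual-averaging step-size adaptation and diagonal
# mass-matrix estimation during warmup. The implementation follows the
# standard slice-variant tree-doubling algorithm; the target density is any
# function returning a log-density and its gradient, which for kinflow
# models is the joint log-posterior with implicit-function-theorem gradients
# through the steady states.

nuts_leapfrog <- function(lp_fn, state, p, eps, inv_m) {
  p_half <- p + 0.5 * eps * state$grad
  z_new <- state$z + eps * inv_m * p_half
  ev <- lp_fn(z_new)
  if (!is.finite(ev$value)) {
    return(list(state = list(z = z_new, lp = -Inf, grad = rep(0, length(z_new))),
                p = p_half))
  }
  list(state = list(z = z_new, lp = ev$value, grad = ev$gradient),
       p = p_half + 0.5 * eps * ev$gradient)
}

nuts_build_tree <- function(lp_fn, state, p, logu, dir, depth, eps, inv_m, H0) {
  if (depth == 0L) {
    lf <- nuts_leapfrog(lp_fn, state, p, dir * eps, inv_m)
    H <- lf$state$lp - 0.5 * sum(lf$p^2 * inv_m)
    if (!is.finite(H)) H <- -Inf
    n <- as.integer(logu <= H)
    div <- (logu - H) > 1000
    list(state_minus = lf$state, p_minus = lf$p,
         state_plus = lf$state, p_plus = lf$p,
         proposal = lf$state, n = n, s = as.integer(!div),
         alpha = min(1, exp(H - H0)), n_alpha = 1L, divergent = div)
  } else {
    t1 <- nuts_build_tree(lp_fn, state, p, logu, dir, depth - 1L, eps, inv_m, H0)
    if (t1$s == 1L) {
      if (dir == -1) {
        t2 <- nuts_build_tree(lp_fn, t1$state_minus, t1$p_minus, logu, dir,
                              depth - 1L, eps, inv_m, H0)
        t1$state_minus <- t2$state_minus; t1$p_minus <- t2$p_minus
      } else {
        t2 <- nuts_build_tree(lp_fn, t1$state_plus, t1$p_plus, logu, dir,
                              depth - 1L, eps, inv_m, H0)
        t1$state_plus <- t2$state_plus; t1$p_plus <- t2$p_plus
      }
      if (t2$n > 0L && stats::runif(1) < t2$n / max(t1$n + t2$n, 1L)) {
        t1$proposal <- t2$proposal
      }
      dz <- t1$state_plus$z - t1$state_minus$z
      ok <- (sum(dz * (inv_m * t1$p_minus)) >= 0) &&
            (sum(dz * (inv_m * t1$p_plus)) >= 0)
      t1$s <- t2$s * as.integer(ok)
      t1$n <- t1$n + t2$n
      t1$alpha <- t1$alpha + t2$alpha
      t1$n_alpha <- t1$n_alpha + t2$n_alpha
      t1$divergent <- t1$divergent || t2$divergent
    }
    t1
  }
}

find_reasonable_epsilon <- function(lp_fn, state, inv_m) {
  eps <- 1
  d <- length(state$z)
  p <- stats::rnorm(d) / sqrt(inv_m)
  H0 <- state$lp - 0.5 * sum(p^2 * inv_m)
  lf <- nuts_leapfrog(lp_fn, state, p, eps, inv_m)
  H1 <- lf$state$lp - 0.5 * sum(lf$p^2 * inv_m)
  if (!is.finite(H1)) {
    while (!is.finite(H1) && eps > 1e-10) {
      eps <- eps / 2
      lf <- nuts_leapfrog(lp_fn, state, p, eps, inv_m)
      H1 <- lf$state$lp - 0.5 * sum(lf$p^2 * inv_m)
    }
    return(max(eps, 1e-10))
  }
  a <- if (H1 - H0 > log(0.5)) 1 else -1
  while (a * (H1 - H0) > -a * log(2)) {
    eps <- eps * 2^a
    if (eps > 1e7 || eps < 1e-10) break
    lf <- nuts_leapfrog(lp_fn, state, p, eps, inv_m)
    H1 <- lf$state$lp - 0.5 * sum(lf$p^2 * inv_m)
    if (!is.finite(H1)) { eps <- eps / 2; break }
  }
  eps
}

#' Low-level No-U-Turn sampler
#'
#' Runs one NUTS chain on an arbitrary differentiable log-density. Used
#' internally by [sample_posterior()]; exposed so that the sampler can be
#' validated against closed-form posteriors.
#'
#' @param lp_fn Function of a numeric vector returning
#'   `list(value, gradient)`; may return `-Inf` to reject a region.
#' @param init Initial point.
#' @param n_warmup,n_draws Warmup (adaptation, discarded) and kept
#'   iterations.
#' @param target_accept Dual-averaging target acceptance statistic.
#' @param max_treedepth Cap on tree doublings per iteration.
#' @param adapt_mass Estimate a diagonal mass matrix during warmup (needs
#'   `n_warmup >= 100`).
#' @return List with `draws` (matrix `n_draws` x dim), `divergent`,
#'   `treedepth`, `accept_stat`, `energy`, `step_size`, `inv_metric`.
#' @export
nuts <- function(lp_fn, init, n_warmup = 1000, n_draws = 1000,
                 target_accept = 0.9, max_treedepth = 10, adapt_mass = TRUE,
                 inv_metric = NULL) {
  d <- length(init)
  ev <- lp_fn(init)
  if (!is.finite(ev$value)) abort("initial point has non-finite log-density.")
  state <- list(z = init, lp = ev$value, grad = ev$gradient)
  inv_m <- inv_metric %||% rep(1, d)

  eps <- find_reasonable_epsilon(lp_fn, state, inv_m)
  mu <- log(10 * eps); log_eps_bar <- 0; H_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75; da_iter <- 0

  # mass-adaptation windows (skipped for very short warmup)
  use_mass <- adapt_mass && n_warmup >= 100
  init_buf <- if (use_mass) max(25L, round(0.15 * n_warmup)) else n_warmup
  term_buf <- if (use_mass) max(20L, round(0.10 * n_warmup)) else 0L
  win_end <- if (use_mass) {
    ends <- integer(0); w <- 25L; pos <- init_buf
    while (pos + w < n_warmup - term_buf) { pos <- pos + w; ends <- c(ends, pos); w <- 2L * w }
    c(ends, n_warmup - term_buf)
  } else integer(0)
  w_n <- 0; w_mean <- rep(0, d); w_m2 <- rep(0, d)

  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, d)
  divergent <- logical(n_draws); treedepth <- integer(n_draws)
  accept_stat <- numeric(n_draws); energy <- numeric(n_draws)

  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d) / sqrt(inv_m)
    H0 <- state$lp - 0.5 * sum(p0^2 * inv_m)
    logu <- H0 - stats::rexp(1)
    minus <- state; plus <- state
    p_minus <- p0; p_plus <- p0
    prop <- state; n <- 1L; s <- 1L; depth <- 0L
    alpha_sum <- 0; n_alpha <- 0L; div <- FALSE
    while (s == 1L && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      tr <- if (dir == -1) {
        nuts_build_tree(lp_fn, minus, p_minus, logu, dir, depth, eps, inv_m, H0)
      } else {
        nuts_build_tree(lp_fn, plus, p_plus, logu, dir, depth, eps, inv_m, H0)
      }
      if (dir == -1) { minus <- tr$state_minus; p_minus <- tr$p_minus }
      else { plus <- tr$state_plus; p_plus <- tr$p_plus }
      if (tr$s == 1L && tr$n > 0L && stats::runif(1) < min(1, tr$n / n)) {
        prop <- tr$proposal
      }
      n <- n + tr$n
      dz <- plus$z - minus$z
      s <- tr$s * as.integer(sum(dz * (inv_m * p_minus)) >= 0 &&
                               sum(dz * (inv_m * p_plus)) >= 0)
      alpha_sum <- alpha_sum + tr$alpha; n_alpha <- n_alpha + tr$n_alpha
      div <- div || tr$divergent
      depth <- depth + 1L
    }
    state <- prop
    a_stat <- alpha_sum / max(n_alpha, 1L)

    if (it <= n_warmup) {
      da_iter <- da_iter + 1
      H_bar <- (1 - 1 / (da_iter + t0)) * H_bar +
        (target_accept - a_stat) / (da_iter + t0)
      log_eps <- mu - sqrt(da_iter) / gamma * H_bar
      w_da <- da_iter^(-kappa)
      log_eps_bar <- w_da * log_eps + (1 - w_da) * log_eps_bar
      eps <- exp(log_eps)
      if (use_mass && it > init_buf && it <= n_warmup - term_buf) {
        w_n <- w_n + 1
        delta <- state$z - w_mean
        w_mean <- w_mean + delta / w_n
        w_m2 <- w_m2 + delta * (state$z - w_mean)
        if (it %in% win_end && w_n > 1) {
          v <- w_m2 / (w_n - 1)
          inv_m <- (w_n / (w_n + 5)) * v + 1e-3 * (5 / (w_n + 5))
          w_n <- 0; w_mean[] <- 0; w_m2[] <- 0
          eps <- find_reasonable_epsilon(lp_fn, state, inv_m)
          mu <- log(10 * eps); log_eps_bar <- 0; H_bar <- 0; da_iter <- 0
        }
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      k <- it - n_warmup
      draws[k, ] <- state$z
      divergent[k] <- div
      treedepth[k] <- depth
      accept_stat[k] <- a_stat
      energy[k] <- -(state$lp)
    }
  }
  list(draws = draws, divergent = divergent, treedepth = treedepth,
       accept_stat = accept_stat, energy = energy,
       step_size = eps, inv_metric = inv_m)
}

#' Sample the joint posterior of a flow-experiment model
#'
#' Runs NUTS chains on the unconstrained parameterization of a
#' [flow_model()], with dual-averaging step-size adaptation (target
#' acceptance 0.9) and diagonal mass estimation during warmup. An analytic
#' gradient check against central finite differences is performed at the
#' first chain's initial point.
#'
#' @param model A `kinflow_model`.
#' @param chains,warmup,draws MCMC run sizes (per chain). At least 2 chains
#'   are needed for convergence diagnostics.
#' @param seed Integer seed; fixed seeds give identical draws.
#' @param target_accept,max_treedepth NUTS tuning (see [nuts()]).
#' @param init `"map"` (default) starts chains from a jittered posterior
#'   mode located by BFGS with the analytic gradient, with the initial
#'   diagonal metric taken from the curvature (finite-differenced gradient)
#'   at the mode; `"prior"` starts from the jittered prior median with a
#'   unit metric. Warmup adaptation refines both.
#' @param init_jitter SD of the Gaussian jitter used to disperse chain
#'   starting points (unconstrained scale).
#' @param loglik Store the pointwise log-likelihood matrix needed for
#'   PSIS-LOO model comparison?
#' @param check_gradient Verify the analytic gradient at initialization.
#'
#' @return A `kinflow_fit`: posterior draws on the natural parameter scale
#'   (`iterations x chains x parameters`), sampler statistics, the pointwise
#'   log-likelihood, and the model. Use [tidy()][generics::tidy],
#'   [glance()][generics::glance], [mcmc_diagnostics()],
#'   [posterior_predictive()].
#' @export
sample_posterior <- function(model, chains = 4, warmup = 1000, draws = 1000,
                             seed = 1, target_accept = 0.9, max_treedepth = 10,
                             init = c("map", "prior"), init_jitter = 0.4,
                             loglik = TRUE, check_gradient = TRUE) {
  stopifnot(inherits(model, "kinflow_model"))
  init <- match.arg(init)
  lp_fn <- function(z) log_posterior(model, z)
  d <- nrow(model$pars)
  z0 <- prior_median_z(model$pars)
  set.seed(as.integer(seed))

  if (check_gradient) {
    ev <- lp_fn(z0)
    if (!is.finite(ev$value)) abort("log-posterior not finite at the prior median.")
    fd <- central_diff(function(z) log_posterior(model, z, grad = FALSE)$value, z0)
    rel <- abs(fd - ev$gradient) / pmax(abs(fd), 1e-6)
    if (max(rel) > 1e-3) {
      abort(sprintf("gradient check failed at initialization (max rel err %.2e, parameter %s).",
                    max(rel), model$pars$param[which.max(rel)]))
    }
  }

  inv_metric <- NULL
  if (init == "map") {
    opt <- tryCatch(
      stats::optim(z0, fn = function(z) -log_posterior(model, z, grad = FALSE)$value,
                   gr = function(z) -log_posterior(model, z)$gradient,
                   method = "BFGS", control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      z0 <- opt$par
      # diagonal curvature at the mode -> initial inverse metric
      h <- vapply(seq_len(d), function(j) {
        eps <- 1e-4 * max(abs(z0[j]), 1)
        zp <- z0; zp[j] <- z0[j] + eps
        zm <- z0; zm[j] <- z0[j] - eps
        (log_posterior(model, zp)$gradient[j] -
           log_posterior(model, zm)$gradient[j]) / (2 * eps)
      }, numeric(1))
      inv_metric <- ifelse(is.finite(h) & h < -1e-8, -1 / h, 1)
      inv_metric <- pmin(pmax(inv_metric, 1e-6), 1e6)
    }
  }

  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init_z <- NULL
    for (try in 1:50) {
      jit_sd <- if (is.null(inv_metric)) init_jitter else init_jitter * sqrt(inv_metric)
      cand <- z0 + stats::rnorm(d, 0, jit_sd)
      if (is.finite(lp_fn(cand)$value)) { init_z <- cand; break }
    }
    if (is.null(init_z)) abort("could not find a feasible initial point.")
    res[[ch]] <- nuts(lp_fn, init_z, n_warmup = warmup, n_draws = draws,
                      target_accept = target_accept,
                      max_treedepth = max_treedepth, inv_metric = inv_metric)
  }

  par_names <- model$pars$param
  arr <- array(NA_real_, c(draws, chains, d),
               dimnames = list(NULL, NULL, par_names))
  stats_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    phi <- t(apply(res[[ch]]$draws, 1,
                   function(z) prior_eval_z(model$pars, z)$phi))
    arr[, ch, ] <- phi
    stats_list[[ch]] <- tibble::tibble(
      chain = ch, iteration = seq_len(draws),
      divergent = res[[ch]]$divergent, treedepth = res[[ch]]$treedepth,
      accept_stat = res[[ch]]$accept_stat, energy = res[[ch]]$energy)
  }
  sampler_stats <- dplyr::bind_rows(stats_list)
  div_frac <- mean(sampler_stats$divergent)
  if (div_frac > 0.1) {
    warn(sprintf("%.0f%% divergent transitions; the posterior geometry is problematic - consider reparameterizing or raising target_accept.",
                 100 * div_frac))
  }

  ll <- NULL
  if (loglik) {
    phi_flat <- do.call(rbind, lapply(seq_len(chains), function(ch) arr[, ch, , drop = TRUE]))
    if (d == 1) phi_flat <- matrix(phi_flat, ncol = 1)
    ll <- model_pointwise_loglik(model, phi_flat)
  }

  structure(
    list(draws = arr, model = model, sampler_stats = sampler_stats,
         loglik = ll, seed = seed,
         settings = list(chains = chains, warmup = warmup, draws = draws,
                         target_accept = target_accept,
                         max_treedepth = max_treedepth),
         step_size = vapply(res, `[[`, numeric(1), "step_size")),
    class = "kinflow_fit"
  )
}

#' @export
print.kinflow_fit <- function(x, ...) {
  cat("<kinflow_fit>\n")
  cat(sprintf("  %d chains x %d draws (warmup %d), %d parameters, seed %s\n",
              x$settings$chains, x$settings$draws, x$settings$warmup,
              dim(x$draws)[3], format(x$seed)))
  cat(sprintf("  divergent transitions: %d (%.1f%%)\n",
              sum(x$sampler_stats$divergent),
              100 * mean(x$sampler_stats$divergent)))
  invisible(x)
}

# draws of one parameter as an iterations x chains matrix
par_draws <- function(fit, param) {
  i <- match(param, dimnames(fit$draws)[[3]])
  if (is.na(i)) abort(sprintf("unknown parameter '%s'.", param))
  fit$draws[, , i, drop = TRUE]
}

# all draws flattened chains-stacked into a draws x parameters matrix
flat_draws <- function(fit) {
  d <- dim(fit$draws)
  out <- do.call(rbind, lapply(seq_len(d[2]), function(ch) fit$draws[, ch, , drop = TRUE]))
  if (d[3] == 1) out <- matrix(out, ncol = 1, dimnames = list(NULL, dimnames(fit$draws)[[3]]))
  out
}
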