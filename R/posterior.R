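#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries
#'
#' One row per free parameter: posterior mean, standard deviation,
#' highest-density interval, and convergence diagnostics.
#'
#' @param x A `kinflow_fit`.
#' @param conf_level Probability mass of the highest-density interval.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`, `ess_bulk`.
#' @export
tidy.kinflow_fit <- function(x, conf_level = 0.94, ...) {
  diag <- mcmc_diagnostics(x)
  purrr::map_dfr(dimnames(x$draws)[[3]], function(p) {
    d <- as.vector(par_draws(x, p))
    h <- hdi_interval(d, conf_level)
    tibble::tibble(term = p, estimate = mean(d), std.error = stats::sd(d),
                   conf.low = h[["lower"]], conf.high = h[["upper"]])
  }) |>
    dplyr::left_join(diag[, c("parameter", "rhat", "ess_bulk")],
                     by = c(term = "parameter"))
}

#' One-line fit summary
#'
#' @param x A `kinflow_fit`.
#' @param ... Unused.
#' @return A one-row tibble: run sizes, divergence count and fraction,
#'   worst R-hat and smallest bulk ESS across parameters.
#' @export
glance.kinflow_fit <- function(x, ...) {
  diag <- mcmc_diagnostics(x)
  tibble::tibble(
    chains = x$settings$chains, draws = x$settings$draws,
    warmup = x$settings$warmup, n_obs = x$model$n_obs,
    n_parameters = dim(x$draws)[3],
    divergences = sum(x$sampler_stats$divergent),
    divergence_rate = mean(x$sampler_stats$divergent),
    max_rhat = max(diag$rhat, na.rm = TRUE),
    min_ess_bulk = min(diag$ess_bulk, na.rm = TRUE))
}

#' @rdname tidy.kinflow_fit
#' @param object A `kinflow_fit`.
#' @export
summary.kinflow_fit <- function(object, ...) tidy(object, ...)

#' Tidy LOO results
#'
#' @param x A `kinflow_loo`.
#' @param ... Unused.
#' @return Pointwise tibble (`elpd`, `khat`, `exact`).
#' @export
tidy.kinflow_loo <- function(x, ...) x$pointwise

#' @rdname tidy.kinflow_loo
#' @export
glance.kinflow_loo <- function(x, ...) {
  tibble::tibble(elpd_loo = x$elpd_loo, se_elpd = x$se_elpd, p_loo = x$p_loo,
                 n_obs = x$n_obs, n_exact = x$n_exact)
}

#' Posterior predictive distribution of the observations
#'
#' Draws replicated observations `g(phi, theta) + Normal(0, sigma_e)` over a
#' thinned subset of posterior draws and summarizes them per observation
#' row with the central 95% (by default) interval.
#'
#' @param fit A `kinflow_fit`.
#' @param experiment_id Restrict to one experiment (default: all).
#' @param n_draws Number of posterior draws used.
#' @param prob Central interval mass.
#' @param summary If `FALSE`, return one row per draw and observation.
#' @param seed Seed for the predictive noise (kept separate from the
#'   sampler's seed).
#' @return The observation rows with `.pred` (posterior mean of the
#'   steady-state prediction), `.lower`, `.upper` interval bounds of the
#'   predictive distribution, and `.covered` (is the observed value inside?).
#' @export
posterior_predictive <- function(fit, experiment_id = NULL, n_draws = 400,
                                 prob = 0.95, summary = TRUE, seed = 1) {
  stopifnot(inherits(fit, "kinflow_fit"))
  obs <- fit$model$observations
  if (!is.null(experiment_id)) {
    if (!experiment_id %in% obs$experiment_id) {
      abort(sprintf("unknown experiment '%s'.", experiment_id))
    }
  }
  phi_all <- flat_draws(fit)
  S <- nrow(phi_all)
  idx <- unique(round(seq(1, S, length.out = min(n_draws, S))))
  set.seed(as.integer(seed))
  sig_cols <- match(paste0("sigma_", obs$experiment_id), colnames(phi_all))
  preds <- matrix(NA_real_, length(idx), nrow(obs))
  reps <- matrix(NA_real_, length(idx), nrow(obs))
  for (s in seq_along(idx)) {
    phi <- phi_all[idx[s], ]
    mu <- model_predict(fit$model, phi)
    preds[s, ] <- mu
    reps[s, ] <- mu + stats::rnorm(nrow(obs), 0, phi[sig_cols])
  }
  keep <- if (is.null(experiment_id)) seq_len(nrow(obs))
          else which(obs$experiment_id == experiment_id)
  if (!summary) {
    return(purrr::map_dfr(seq_along(idx), function(s) {
      dplyr::mutate(obs[keep, ], .draw = s, .pred = preds[s, keep],
                    .rep = reps[s, keep])
    }))
  }
  a <- (1 - prob) / 2
  out <- obs[keep, ]
  out$.pred <- colMeans(preds[, keep, drop = FALSE], na.rm = TRUE)
  out$.lower <- apply(reps[, keep, drop = FALSE], 2, stats::quantile,
                      probs = a, na.rm = TRUE)
  out$.upper <- apply(reps[, keep, drop = FALSE], 2, stats::quantile,
                      probs = 1 - a, na.rm = TRUE)
  out$.covered <- out$value >= out$.lower & out$value <= out$.upper
  out
}

#' Rank experiments by their inferred noise level
#'
#' The per-experiment uncertainty parameters act as automatic weighting
#' factors: experiments whose observations disagree with the rest of the
#' data absorb the discrepancy into a large `sigma_e`. Ranking the posterior
#' medians of `sigma_e` against their cross-experiment median flags likely
#' outlier experiments.
#'
#' @param fit A `kinflow_fit`.
#' @param threshold Flag experiments whose median `sigma_e` exceeds
#'   `threshold` times the cross-experiment median.
#' @return Tibble ranked by `sigma_median` (descending) with `ratio_to_median`
#'   and `flagged`; carries attribute `applicable = FALSE` (and an empty
#'   flag column) when fewer than two experiments are present.
#' @export
flag_outlier_experiments <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "kinflow_fit"))
  exps <- unique(fit$model$observations$experiment_id)
  med <- vapply(exps, function(e) {
    stats::median(as.vector(par_draws(fit, paste0("sigma_", e))))
  }, numeric(1))
  out <- tibble::tibble(experiment_id = exps, sigma_median = med)
  if (length(exps) < 2) {
    out$ratio_to_median <- NA_real_
    out$flagged <- NA
    attr(out, "applicable") <- FALSE
    return(out)
  }
  overall <- stats::median(med)
  out$ratio_to_median <- med / overall
  out$flagged <- out$ratio_to_median > threshold
  out <- dplyr::arrange(out, dplyr::desc(.data$sigma_median))
  out$rank <- seq_len(nrow(out))
  attr(out, "applicable") <- TRUE
  out
}

#' Posterior pairwise correlations
#'
#' Spearman rank correlations between posterior draws of the kinetic
#' parameters; the off-diagonal structure mirrors how experiments couple
#' parameters (e.g. turnover number against inhibition constant when an
#' inhibitor is present).
#'
#' @param fit A `kinflow_fit`.
#' @param pars Parameters to include (default: all kinetic parameters).
#' @return Correlation matrix.
#' @export
posterior_correlations <- function(fit, pars = NULL) {
  pars <- pars %||% fit$model$pars$param[fit$model$pars$kind == "kinetic"]
  m <- flat_draws(fit)[, pars, drop = FALSE]
  stats::cor(m, method = "spearman")
}

# ---------------------------------------------------------------------------
# plotting

#' Plot posterior marginals or traces
#'
#' @param object A `kinflow_fit`.
#' @param pars Parameters to show (default: kinetic parameters).
#' @param type `"density"` or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinflow_fit <- function(object, pars = NULL,
                                 type = c("density", "trace"), ...) {
  type <- match.arg(type)
  pars <- pars %||% object$model$pars$param[object$model$pars$kind == "kinetic"]
  df <- purrr::map_dfr(pars, function(p) {
    x <- par_draws(object, p)
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    purrr::map_dfr(seq_len(ncol(x)), function(ch) {
      tibble::tibble(parameter = p, chain = factor(ch),
                     iteration = seq_len(nrow(x)), value = x[, ch])
    })
  })
  if (type == "density") {
    ggplot2::ggplot(df, ggplot2::aes(.data$value, colour = .data$chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                     colour = .data$chain)) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(y = NULL)
  }
}

#' Pairwise posterior scatter plots
#'
#' @param fit A `kinflow_fit`.
#' @param pars Two or more parameter names.
#' @param n_draws Thin to this many draws.
#' @return A ggplot object (facet grid of parameter pairs).
#' @export
plot_pairs <- function(fit, pars, n_draws = 1000) {
  stopifnot(length(pars) >= 2)
  m <- flat_draws(fit)[, pars, drop = FALSE]
  idx <- unique(round(seq(1, nrow(m), length.out = min(n_draws, nrow(m)))))
  m <- m[idx, , drop = FALSE]
  cmb <- utils::combn(pars, 2)
  df <- purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
    tibble::tibble(pair = paste(cmb[1, i], "vs", cmb[2, i]),
                   x = m[, cmb[1, i]], y = m[, cmb[2, i]])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot posterior predictive intervals against observations
#'
#' @param fit A `kinflow_fit`.
#' @param experiment_id Experiment to display (default: all).
#' @param ... Passed to [posterior_predictive()].
#' @return A ggplot object: observed values with 95% predictive intervals.
#' @export
plot_posterior_predictive <- function(fit, experiment_id = NULL, ...) {
  pp <- posterior_predictive(fit, experiment_id = experiment_id, ...)
  pp$.index <- seq_len(nrow(pp))
  ggplot2::ggplot(pp, ggplot2::aes(.data$.index)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$.lower, ymax = .data$.upper),
                           width = 0.3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$.pred), shape = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value, colour = .data$experiment_id)) +
    ggplot2::labs(x = "observation", y = "concentration (uM)",
                  colour = "experiment")
}

#' Plot a model comparison
#'
#' Ranked elpd estimates with standard errors, and the standard error of the
#' difference to the top-ranked model.
#'
#' @param object A `kinflow_loo_compare` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinflow_loo_compare <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model <- stats::reorder(df$model, df$elpd_loo)
  ggplot2::ggplot(df, ggplot2::aes(.data$elpd_loo, .data$model)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$elpd_loo - .data$se_elpd,
                                         xmax = .data$elpd_loo + .data$se_elpd),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$elpd_loo - .data$se_diff,
                                         xmax = .data$elpd_loo + .data$se_diff),
                            height = 0.1, colour = "grey60") +
    ggplot2::labs(x = "elpd (PSIS-LOO)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
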