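# Joint Bayesian model: priors over all free parameters, Gaussian
# steady-state observation likelihood with one noise parameter per
# experiment, and combination of heterogeneous experiments/topologies with
# shared, batch-specific and per-experiment parameters.

obs_required_cols <- c("experiment_id", "topology_id", "k_f",
                       "observed_species", "value")

validate_observations <- function(observations) {
  observations <- tibble::as_tibble(observations)
  missing <- setdiff(obs_required_cols, names(observations))
  if (length(missing)) {
    abort(sprintf("observation table lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(observations$value) | observations$value < 0)
  if (length(bad)) {
    abort(sprintf("observation row %d has a negative or non-finite value.", bad[1]))
  }
  for (tid in unique(observations$topology_id)) {
    net <- topology(tid)
    sp <- unique(observations$observed_species[observations$topology_id == tid])
    off <- setdiff(sp, net$observables)
    if (length(off)) {
      abort(sprintf("species %s not observable in topology '%s'.",
                    paste(off, collapse = ", "), tid))
    }
  }
  observations
}

#' Default parameter map for an observation table
#'
#' Binds every rate-law role of every topology present in the data to a
#' global parameter named `<enzyme>_<role>`, shared across all experiments.
#' Batch-specific parameters (e.g. two enzyme batches with distinct turnover
#' numbers but a common Michaelis constant) are declared by adding rows with
#' a non-`NA` `experiment_id`, which override the topology-wide binding for
#' those experiments.
#'
#' @param observations Observation table (see [flow_model()]).
#' @return A tibble with columns `topology_id`, `enzyme`, `role`, `param`,
#'   `experiment_id`.
#' @export
default_parameter_map <- function(observations) {
  observations <- tibble::as_tibble(observations)
  purrr::map_dfr(unique(observations$topology_id), function(tid) {
    net <- topology(tid)
    purrr::map_dfr(net$reactions, function(rx) {
      tibble::tibble(topology_id = tid, enzyme = rx$enzyme, role = rx$roles,
                     param = paste(rx$enzyme, rx$roles, sep = "_"),
                     experiment_id = NA_character_)
    })
  })
}

default_prior_for <- function(param, role) {
  if (grepl("^kcat", role)) return(prior_spec(param, "lognormal", log(10), 1))
  if (grepl("^Km", role)) return(prior_spec(param, "lognormal", log(100), 1))
  if (role == "Ki") return(prior_spec(param, "uniform", 1, 1e4))
  if (role == "hill") return(prior_spec(param, "uniform", 1, 5))
  prior_spec(param, "lognormal", log(10), 1)
}

#' Build the joint posterior model for a set of flow experiments
#'
#' Combines all observations into a single probabilistic model: each
#' observation `y` contributes a Gaussian likelihood term
#' `Normal(y | g_species(phi, theta), sigma_e)` where `g` is the steady-state
#' map of the observation's topology at its conditions and `sigma_e` is the
#' noise parameter of its experiment. Unobserved species contribute no term,
#' so partially observed topologies (e.g. the combined GDH+HK reactor where
#' only NADH is detected) still inform every parameter they touch.
#'
#' @param observations Tibble with columns `experiment_id`, `topology_id`,
#'   `k_f`, `inflow_<species>` (absent columns default to 0),
#'   `enz_<enzyme>` (default 1), `observed_species`, `value`, and optionally
#'   `replicate`. Each replicate is an independent likelihood term.
#' @param parameter_map Binding of rate-law roles to global parameter names;
#'   defaults to [default_parameter_map()]. Rows with an `experiment_id`
#'   override the shared binding for that experiment (enzyme batches).
#' @param priors Tibble of [prior_spec()] rows. Parameters without an entry
#'   get defaults: log-normal(log 10, 1) for turnover numbers,
#'   log-normal(log 100, 1) for Michaelis constants, uniform(1, 10^4) uM for
#'   inhibition constants, uniform(1, 5) for Hill exponents, and
#'   half-normal scaled by each experiment's observed standard deviation for
#'   the noise parameters `sigma_<experiment>`.
#' @param free_conditions Optional tibble (`experiment_id`, `species`,
#'   `param`) promoting an inflow concentration from a fixed control to a
#'   free parameter with an informed prior (supply the prior in `priors`).
#' @param quiet Suppress the message listing defaulted priors.
#'
#' @return A `kinflow_model` object; see [log_posterior()],
#'   [sample_posterior()].
#' @export
flow_model <- function(observations, parameter_map = NULL, priors = NULL,
                       free_conditions = NULL, quiet = FALSE) {
  observations <- validate_observations(observations)
  map <- parameter_map %||% default_parameter_map(observations)
  map <- tibble::as_tibble(map)
  if (!("experiment_id" %in% names(map))) map$experiment_id <- NA_character_

  experiments <- unique(observations$experiment_id)
  sigma_params <- paste0("sigma_", experiments)

  kin_params <- unique(map$param)
  cond_params <- if (!is.null(free_conditions)) unique(free_conditions$param) else character()

  # resolve priors: user-specified rows win, otherwise role-based defaults
  user <- if (is.null(priors)) tibble::tibble(param = character(), dist = character(),
                                              a = numeric(), b = numeric())
          else tibble::as_tibble(priors)
  defaulted <- character()
  prior_rows <- list()
  for (p in kin_params) {
    if (p %in% user$param) {
      prior_rows[[p]] <- user[user$param == p, c("param", "dist", "a", "b")][1, ]
    } else {
      role <- map$role[map$param == p][1]
      prior_rows[[p]] <- default_prior_for(p, role)
      defaulted <- c(defaulted, p)
    }
  }
  for (e in experiments) {
    p <- paste0("sigma_", e)
    if (p %in% user$param) {
      prior_rows[[p]] <- user[user$param == p, c("param", "dist", "a", "b")][1, ]
    } else {
      v <- observations$value[observations$experiment_id == e]
      sc <- stats::sd(v)
      if (!is.finite(sc) || sc <= 0) sc <- max(1, 0.1 * mean(v))
      prior_rows[[p]] <- prior_spec(p, "halfnormal", sc)
      defaulted <- c(defaulted, p)
    }
  }
  for (p in cond_params) {
    if (!(p %in% user$param)) {
      abort(sprintf("free condition parameter '%s' needs an informed prior.", p))
    }
    prior_rows[[p]] <- user[user$param == p, c("param", "dist", "a", "b")][1, ]
  }
  pars <- dplyr::bind_rows(prior_rows)
  pars$kind <- dplyr::case_when(
    pars$param %in% sigma_params ~ "sigma",
    pars$param %in% cond_params ~ "condition",
    TRUE ~ "kinetic")
  pars$transform <- prior_transform(pars$dist)
  if (!quiet && length(defaulted)) {
    inform(sprintf("default priors applied to: %s", paste(defaulted, collapse = ", ")))
  }
  par_index <- stats::setNames(seq_len(nrow(pars)), pars$param)

  # compile per-topology groups of condition blocks
  obs <- observations
  obs$.obs <- seq_len(nrow(obs))
  groups <- list()
  for (tid in unique(obs$topology_id)) {
    net <- topology(tid)
    sub <- obs[obs$topology_id == tid, ]
    cond_cols <- intersect(names(sub),
                           c("k_f", paste0("inflow_", net$species),
                             paste0("enz_", net$enzymes)))
    key <- do.call(paste, c(sub[c("experiment_id", cond_cols)], sep = "\r"))
    block_of <- match(key, unique(key))
    first <- !duplicated(key)
    blocks <- sub[first, c("experiment_id", cond_cols)]
    cm <- conditions_matrices(blocks, net)
    nb <- nrow(blocks)

    bind <- vector("list", length(net$reactions))
    for (r in seq_along(net$reactions)) {
      rx <- net$reactions[[r]]
      m <- matrix(0L, nb, length(rx$roles))
      for (j in seq_along(rx$roles)) {
        rows <- map[map$topology_id == tid & map$enzyme == rx$enzyme &
                      map$role == rx$roles[j], ]
        if (!nrow(rows)) {
          abort(sprintf("parameter map misses role '%s' of enzyme '%s' in topology '%s'.",
                        rx$roles[j], rx$enzyme, tid))
        }
        shared <- rows$param[is.na(rows$experiment_id)]
        for (bi in seq_len(nb)) {
          specific <- rows$param[!is.na(rows$experiment_id) &
                                   rows$experiment_id == blocks$experiment_id[bi]]
          pname <- if (length(specific)) specific[1] else shared[1]
          if (is.na(pname) || is.null(pname)) {
            abort(sprintf("no binding for role '%s' (enzyme %s) in experiment '%s'.",
                          rx$roles[j], rx$enzyme, blocks$experiment_id[bi]))
          }
          m[bi, j] <- par_index[[pname]]
        }
      }
      bind[[r]] <- m
    }

    cond_free <- NULL
    if (!is.null(free_conditions)) {
      fc <- tibble::as_tibble(free_conditions)
      fc <- fc[fc$experiment_id %in% blocks$experiment_id &
                 fc$species %in% net$species, , drop = FALSE]
      if (nrow(fc)) {
        cond_free <- purrr::map_dfr(seq_len(nrow(fc)), function(i) {
          tibble::tibble(
            block = which(blocks$experiment_id == fc$experiment_id[i]),
            species = match(fc$species[i], net$species),
            par = unname(par_index[[fc$param[i]]]))
        })
      }
    }

    groups[[tid]] <- list(
      net = net, nb = nb, C_in = cm$C_in, k_f = cm$k_f, Enz = cm$Enz,
      experiment = blocks$experiment_id, bind = bind,
      cond_free = cond_free,
      obs_block = block_of,
      obs_sp = match(sub$observed_species, net$species),
      obs_sig = unname(par_index[paste0("sigma_", sub$experiment_id)]),
      obs_y = sub$value,
      obs_row = sub$.obs,
      analytic = analytic_supported(net)
    )
  }

  # orphan check: every free parameter must be reachable from some term
  touched <- unique(c(
    unlist(lapply(groups, function(g) lapply(g$bind, as.vector))),
    unlist(lapply(groups, function(g) g$obs_sig)),
    unlist(lapply(groups, function(g) if (!is.null(g$cond_free)) g$cond_free$par))
  ))
  orphans <- setdiff(seq_len(nrow(pars)), touched)
  if (length(orphans)) {
    warn(sprintf("parameters not reached by any likelihood term: %s",
                 paste(pars$param[orphans], collapse = ", ")))
  }

  structure(
    list(observations = observations, parameter_map = map, pars = pars,
         pars_plain = list(dist = pars$dist, a = pars$a, b = pars$b,
                           transform = pars$transform),
         groups = groups, n_obs = nrow(observations),
         free_conditions = free_conditions, priors_resolved = pars),
    class = "kinflow_model"
  )
}

#' @export
print.kinflow_model <- function(x, ...) {
  cat("<kinflow_model>\n")
  cat(sprintf("  observations: %d across %d experiment(s), %d topolog%s\n",
              x$n_obs, length(unique(x$observations$experiment_id)),
              length(x$groups), if (length(x$groups) == 1) "y" else "ies"))
  cat(sprintf("  free parameters: %d (%d kinetic, %d noise, %d condition)\n",
              nrow(x$pars), sum(x$pars$kind == "kinetic"),
              sum(x$pars$kind == "sigma"), sum(x$pars$kind == "condition")))
  invisible(x)
}

#' Model parameters
#'
#' @param model A `kinflow_model`.
#' @return Tibble of free parameters with priors and sampling transforms.
#' @export
model_parameters <- function(model) model$pars

# forward solve of all groups; returns list of solutions or NULL on failure
model_solve_groups <- function(model, phi) {
  sols <- vector("list", length(model$groups))
  names(sols) <- names(model$groups)
  for (gi in seq_along(model$groups)) {
    g <- model$groups[[gi]]
    Ps <- lapply(seq_along(g$net$reactions), function(r) {
      m <- matrix(phi[g$bind[[r]]], g$nb)
      colnames(m) <- g$net$reactions[[r]]$roles
      m
    })
    C_in <- g$C_in
    if (!is.null(g$cond_free)) {
      C_in[cbind(g$cond_free$block, g$cond_free$species)] <- phi[g$cond_free$par]
    }
    sol <- if (g$analytic) ss_solve_analytic(g$net, Ps, g$Enz, C_in, g$k_f)
           else ss_solve_newton(g$net, Ps, g$Enz, C_in, g$k_f)
    if (!all(sol$converged)) return(NULL)
    sol$Ps <- Ps
    sol$C_in_eff <- C_in
    sols[[gi]] <- sol
  }
  sols
}

#' Log-posterior density and gradient
#'
#' Evaluates the joint log-posterior in the unconstrained sampling space
#' (log / scaled-logit transforms per prior; transform Jacobians included).
#' Gradients flow through the steady states via implicit-function-theorem
#' sensitivities. Steady-state non-convergence yields `-Inf` (the sampler
#' rejects such proposals).
#'
#' @param model A `kinflow_model`.
#' @param z Numeric vector in the unconstrained space, ordered as
#'   [model_parameters()].
#' @param grad Compute the gradient as well?
#' @return List with `value` and (if requested) `gradient`.
#' @export
log_posterior <- function(model, z, grad = TRUE) {
  pr <- prior_eval_z(model$pars_plain %||% model$pars, z)
  phi <- pr$phi
  if (any(!is.finite(phi)) ||
      any(phi <= 0 & (model$pars_plain %||% model$pars)$transform == "log")) {
    return(list(value = -Inf,
                gradient = if (grad) rep(0, length(z)) else NULL))
  }
  lp <- sum(pr$lp)
  gphi <- numeric(length(phi))
  sols <- model_solve_groups(model, phi)
  if (is.null(sols)) {
    return(list(value = -Inf,
                gradient = if (grad) rep(0, length(z)) else NULL))
  }
  for (gi in seq_along(model$groups)) {
    g <- model$groups[[gi]]
    sol <- sols[[gi]]
    pred <- sol$C[cbind(g$obs_block, g$obs_sp)]
    sigma <- phi[g$obs_sig]
    resid <- g$obs_y - pred
    lp <- lp + sum(-log(sigma) - 0.5 * log(2 * pi) - 0.5 * (resid / sigma)^2)
    if (grad) {
      w <- resid / sigma^2  # d loglik / d pred
      R <- length(g$net$reactions)
      if (R <= 2L && is.null(g$cond_free)) {
        # fast path: chain rule directly at the observed entries
        J <- ss_newton_jacobian(g$net, sol$pieces, g$k_f)
        if (R == 1L) {
          # dx/dtheta = dP / (k_f J); dpred = N[sp, 1] * dx
          dx <- sol$pieces$dP[[1]] / (g$k_f * J[, 1, 1])
          nsp <- g$net$stoich[g$obs_sp, 1]
          contrib <- (w * nsp) * dx[g$obs_block, , drop = FALSE]
          idx <- g$bind[[1]][g$obs_block, , drop = FALSE]
          agg <- rowsum(as.vector(contrib), as.vector(idx))
          ii <- as.integer(rownames(agg))
          gphi[ii] <- gphi[ii] + agg[, 1]
        } else {
          det <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
          # columns of J^{-1}: response of x to a unit source in reaction r
          Jinv <- list(cbind(J[, 2, 2] / det, -J[, 2, 1] / det),
                       cbind(-J[, 1, 2] / det, J[, 1, 1] / det))
          N1 <- g$net$stoich[g$obs_sp, 1]; N2 <- g$net$stoich[g$obs_sp, 2]
          for (r in 1:2) {
            dPk <- sol$pieces$dP[[r]] / g$k_f
            # dpred = (N1 Jinv[1,r] + N2 Jinv[2,r])[block] * dP_r
            fac <- N1 * Jinv[[r]][g$obs_block, 1] + N2 * Jinv[[r]][g$obs_block, 2]
            contrib <- (w * fac) * dPk[g$obs_block, , drop = FALSE]
            idx <- g$bind[[r]][g$obs_block, , drop = FALSE]
            agg <- rowsum(as.vector(contrib), as.vector(idx))
            ii <- as.integer(rownames(agg))
            gphi[ii] <- gphi[ii] + agg[, 1]
          }
        }
        sens <- NULL
      } else {
        wrt_inflow <- if (!is.null(g$cond_free))
          g$net$species[unique(g$cond_free$species)] else NULL
        sens <- ss_sensitivities_core(g$net, sol, g$k_f, wrt_inflow = wrt_inflow)
        off <- 0L
        for (r in seq_along(g$net$reactions)) {
          nr <- length(g$net$reactions[[r]]$roles)
          for (j in seq_len(nr)) {
            dpred <- sens$dC[cbind(g$obs_block, g$obs_sp, off + j)]
            idx <- g$bind[[r]][g$obs_block, j]
            agg <- rowsum(w * dpred, idx)
            gphi[as.integer(rownames(agg))] <-
              gphi[as.integer(rownames(agg))] + agg[, 1]
          }
          off <- off + nr
        }
      }
      dsig <- -1 / sigma + resid^2 / sigma^3
      agg <- rowsum(dsig, g$obs_sig)
      gphi[as.integer(rownames(agg))] <- gphi[as.integer(rownames(agg))] + agg[, 1]
      if (!is.null(g$cond_free)) {
        for (i in seq_len(nrow(g$cond_free))) {
          bi <- g$cond_free$block[i]
          spname <- g$net$species[g$cond_free$species[i]]
          on_block <- which(g$obs_block == bi)
          if (!length(on_block)) next
          dpred <- sens$dC_in[cbind(bi, g$obs_sp[on_block],
                                    match(spname, dimnames(sens$dC_in)[[3]]))]
          gphi[g$cond_free$par[i]] <- gphi[g$cond_free$par[i]] +
            sum(w[on_block] * dpred)
        }
      }
    }
  }
  if (!grad) return(list(value = lp))
  list(value = lp, gradient = pr$dlp + gphi * pr$dphi)
}

# pointwise Gaussian log-likelihood matrix: draws x observations
model_pointwise_loglik <- function(model, phi_draws) {
  n_draw <- nrow(phi_draws)
  out <- matrix(NA_real_, n_draw, model$n_obs)
  for (s in seq_len(n_draw)) {
    phi <- phi_draws[s, ]
    sols <- model_solve_groups(model, phi)
    if (is.null(sols)) next
    for (gi in seq_along(model$groups)) {
      g <- model$groups[[gi]]
      pred <- sols[[gi]]$C[cbind(g$obs_block, g$obs_sp)]
      sigma <- phi[g$obs_sig]
      out[s, g$obs_row] <- stats::dnorm(g$obs_y, pred, sigma, log = TRUE)
    }
  }
  out
}

# deterministic steady-state predictions for each observation at phi
model_predict <- function(model, phi) {
  sols <- model_solve_groups(model, phi)
  if (is.null(sols)) return(rep(NA_real_, model$n_obs))
  pred <- numeric(model$n_obs)
  for (gi in seq_along(model$groups)) {
    g <- model$groups[[gi]]
    pred[g$obs_row] <- sols[[gi]]$C[cbind(g$obs_block, g$obs_sp)]
  }
  pred
}
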