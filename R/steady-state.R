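# CSTR steady-state machinery.
#
# The reactor ODE for species vector C is
#   dC/dt = k_f (C_in - C) + N v(C)
# with N the species-by-reaction stoichiometry and v the rate-law vector.
# Steady states are found in reaction-extent space: writing x_r = v_r / k_f,
# the fixed point satisfies C = C_in + N x and
#   g(x) = x - v(C_in + N x) / k_f = 0.
# This keeps the stoichiometric conservation relations exact, reduces the
# problem to one unknown per reaction, and lets many condition sets be solved
# simultaneously (rows are independent). dv_r/dx_r <= 0 for the laws used
# here, so the Newton Jacobian I - (1/k_f) dv/dC N has unit-dominant diagonal.

# rate vector + derivative pieces at concentrations C (n x species);
# `what` controls how much is computed: "v" (rates), "jac" (+ concentration
# derivatives for the Newton Jacobian), "all" (+ parameter derivatives)
ss_rate_pieces <- function(net, Ps, Enz, C, k_f, what = "all") {
  R <- length(net$reactions)
  n <- nrow(C)
  v <- matrix(0, n, R)
  dC_slots <- vector("list", R)
  dP <- vector("list", R)
  for (r in seq_len(R)) {
    rx <- net$reactions[[r]]
    law <- rate_law(rx$law)
    Cs <- C[, rx$slot_idx, drop = FALSE]
    E <- Enz[, rx$enzyme]
    v[, r] <- law$rate(Cs, Ps[[r]], E)
    if (what != "v") {
      dC_slots[[r]] <- law$d_conc(Cs, Ps[[r]], E)
      if (what == "all") dP[[r]] <- law$d_par(Cs, Ps[[r]], E)
    }
  }
  list(v = v, dC_slots = dC_slots, dP = dP)
}

row_max_abs <- function(m) {
  if (ncol(m) == 1L) return(abs(m[, 1]))
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) abs(m[, j])))
}

row_min <- function(m) {
  if (ncol(m) == 1L) return(m[, 1])
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

row_max <- function(m) {
  if (ncol(m) == 1L) return(m[, 1])
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Newton Jacobian J[n, R, R] of g(x): delta_rq - (1/k_f) sum_s dv_r/dC_s N[s,q]
ss_newton_jacobian <- function(net, pieces, k_f) {
  R <- length(net$reactions)
  n <- length(k_f)
  J <- array(0, c(n, R, R))
  for (r in seq_len(R)) {
    rx <- net$reactions[[r]]
    Nsub <- net$stoich[rx$slot_idx, , drop = FALSE]  # slots x R
    D <- pieces$dC_slots[[r]] %*% Nsub               # n x R
    J[, r, ] <- -D / k_f
    J[, r, r] <- J[, r, r] + 1
  }
  J
}

# solve J[i,,] %*% delta[i,] = b[i,] for all rows; closed form for R <= 2
batch_solve <- function(J, b) {
  R <- dim(J)[2]
  if (R == 1) return(cbind(b[, 1] / J[, 1, 1]))
  if (R == 2) {
    det <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
    cbind((J[, 2, 2] * b[, 1] - J[, 1, 2] * b[, 2]) / det,
          (-J[, 2, 1] * b[, 1] + J[, 1, 1] * b[, 2]) / det)
  } else {
    t(vapply(seq_len(dim(J)[1]),
             function(i) solve(J[i, , ], b[i, ]), numeric(R)))
  }
}

# specialized scalar-extent Newton for single-reaction topologies; pure
# vector operations over condition rows
ss_solve_newton1 <- function(net, Ps, Enz, C_in, k_f,
                             atol = 1e-12, rtol = 1e-12, max_iter = 60L) {
  rx <- net$reactions[[1]]
  law <- rate_law(rx$law)
  P <- Ps[[1]]
  E <- Enz[, rx$enzyme]
  n <- nrow(C_in)
  Nfull <- net$stoich[, 1]
  slots <- rx$slot_idx
  Nslot <- Nfull[slots]
  cons_idx <- which(Nfull < 0)  # only consumed species can go negative
  Cin_slots <- C_in[, slots, drop = FALSE]
  # upper bound on the extent: smallest consumed pool
  x_max <- if (length(cons_idx)) {
    do.call(pmin, lapply(cons_idx, function(j) C_in[, j] / (-Nfull[j])))
  } else rep(Inf, n)
  scale <- do.call(pmax, c(lapply(seq_len(ncol(C_in)), function(j) C_in[, j]),
                           list(1)))
  tol <- atol + rtol * scale
  rate_fn <- law$rate
  dconc_fn <- law$d_conc
  x <- numeric(n)
  g <- x - rate_fn(Cin_slots, P, E) / k_f
  g[is.na(g)] <- Inf
  active <- abs(g) > tol
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    Cs <- Cin_slots + outer(x, Nslot)
    dvdx <- as.vector(dconc_fn(Cs, P, E) %*% Nslot)
    J <- 1 - dvdx / k_f
    delta <- ifelse(active, g / J, 0)
    delta[!is.finite(delta)] <- 0
    step <- rep(1, n)
    settled <- !active
    x_new <- x; g_new <- g
    tries <- 0L
    while (!all(settled) && tries < 30L) {
      tries <- tries + 1L
      x_try <- pmin(pmax(x - step * delta, 0), x_max)
      g_try <- x_try - rate_fn(Cin_slots + outer(x_try, Nslot), P, E) / k_f
      g_try[is.na(g_try)] <- Inf
      ok <- !settled & (abs(g_try) <= abs(g) | abs(g_try) <= tol)
      x_new[ok] <- x_try[ok]
      g_new[ok] <- g_try[ok]
      settled <- settled | ok | (step < 1e-12)
      step[!settled] <- step[!settled] / 2
    }
    x <- x_new; g <- g_new
    active <- abs(g) > tol
  }
  C <- C_in + outer(x, Nfull)
  C[C < 0] <- 0
  pieces <- ss_rate_pieces(net, Ps, Enz, C, k_f, what = "all")
  list(C = C, x = cbind(x), converged = abs(g) <= tol,
       residual = abs(g) * k_f, pieces = pieces, iter = iter)
}

ss_solve_newton <- function(net, Ps, Enz, C_in, k_f,
                            atol = 1e-12, rtol = 1e-12, max_iter = 60L) {
  n <- nrow(C_in)
  R <- length(net$reactions)
  if (R == 1L) {
    return(ss_solve_newton1(net, Ps, Enz, C_in, k_f, atol, rtol, max_iter))
  }
  Nt <- t(net$stoich)
  x <- matrix(0, n, R)
  scale <- pmax(row_max(C_in), 1)
  tol <- atol + rtol * scale
  C <- C_in
  pieces <- ss_rate_pieces(net, Ps, Enz, C, k_f, what = "jac")
  g <- x - pieces$v / k_f
  gnorm <- row_max_abs(g)
  gnorm[is.na(gnorm)] <- Inf
  active <- gnorm > tol
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    J <- ss_newton_jacobian(net, pieces, k_f)
    delta <- batch_solve(J, g)
    delta[!active, ] <- 0
    delta[!is.finite(delta)] <- 0
    # per-row step halving: candidate must stay feasible (C >= 0) and not
    # increase the residual; stalled rows keep their current iterate
    step <- rep(1, n)
    settled <- !active
    x_new <- x; C_new <- C; g_new <- g; gnorm_new <- gnorm
    tries <- 0L
    while (!all(settled) && tries < 30L) {
      tries <- tries + 1L
      x_try <- x - step * delta
      C_try <- C_in + x_try %*% Nt
      feas <- row_min(C_try) >= -1e-12 * scale
      C_try[C_try < 0] <- 0
      v_try <- ss_rate_pieces(net, Ps, Enz, C_try, k_f, what = "v")$v
      g_try <- x_try - v_try / k_f
      gn_try <- row_max_abs(g_try)
      gn_try[is.na(gn_try)] <- Inf
      ok <- !settled & feas & (gn_try <= gnorm | gn_try <= tol)
      if (any(ok)) {
        x_new[ok, ] <- x_try[ok, , drop = FALSE]
        C_new[ok, ] <- C_try[ok, , drop = FALSE]
        g_new[ok, ] <- g_try[ok, , drop = FALSE]
        gnorm_new[ok] <- gn_try[ok]
        settled <- settled | ok
      }
      stalled <- !settled & step < 1e-12
      settled <- settled | stalled
      step[!settled] <- step[!settled] / 2
    }
    x <- x_new; C <- C_new; g <- g_new; gnorm <- gnorm_new
    active <- gnorm > tol
    if (any(active) || iter == max_iter) {
      pieces <- ss_rate_pieces(net, Ps, Enz, C, k_f, what = "jac")
      g <- x - pieces$v / k_f
      gnorm <- row_max_abs(g)
      gnorm[is.na(gnorm)] <- Inf
      active <- gnorm > tol
    }
  }
  pieces <- ss_rate_pieces(net, Ps, Enz, C, k_f, what = "all")
  list(C = C, x = x, converged = gnorm <= tol,
       residual = gnorm * k_f, pieces = pieces, iter = iter)
}

# closed-form steady state for single-reaction mm / mm_uncompetitive networks
ss_solve_analytic <- function(net, Ps, Enz, C_in, k_f) {
  rx <- net$reactions[[1]]
  if (!(length(net$reactions) == 1 && rx$law %in% c("mm", "mm_uncompetitive"))) {
    abort("analytic steady state supports single-reaction 'mm' and 'mm_uncompetitive' topologies only.",
          class = "kinflow_not_supported")
  }
  P <- Ps[[1]]
  vmax <- P[, 1] * Enz[, rx$enzyme]
  km <- P[, 2]
  s_idx <- match(rx$substrates, net$species)
  S_in <- C_in[, s_idx]
  alpha <- if (rx$law == "mm_uncompetitive") {
    i_idx <- match(rx$modifiers, net$species)
    1 + C_in[, i_idx] / P[, 3]
  } else rep(1, nrow(C_in))
  # k_f a S^2 + (k_f Km + Vmax - k_f a S_in) S - k_f Km S_in = 0
  a <- k_f * alpha
  b <- k_f * km + vmax - k_f * alpha * S_in
  cc <- -k_f * km * S_in
  disc <- sqrt(pmax(b^2 - 4 * a * cc, 0))
  q <- -(b + sign(b + (b == 0)) * disc) / 2
  r1 <- q / a
  r2 <- ifelse(q != 0, cc / q, 0)
  S <- pmax(pmin(ifelse(r1 >= 0 & r1 <= S_in + 1e-9, r1, r2), S_in), 0)
  S[vmax == 0] <- S_in[vmax == 0]
  S[S_in == 0] <- 0
  x <- cbind(S_in - S)  # single-reaction extent
  C <- C_in + x %*% t(net$stoich)
  C[, s_idx] <- S
  pieces <- ss_rate_pieces(net, Ps, Enz, C, k_f)
  g <- x - pieces$v / k_f
  list(C = C, x = x, converged = rep(TRUE, nrow(C)),
       residual = row_max_abs(g) * k_f, pieces = pieces, iter = 0L)
}

analytic_supported <- function(net) {
  length(net$reactions) == 1 && net$reactions[[1]]$law %in% c("mm", "mm_uncompetitive")
}

# time-integration fallback / oracle: integrate the reactor ODEs until the
# relative change over a residence time drops below `reltol`
ss_solve_integrate <- function(net, Ps, Enz, C_in, k_f, reltol = 1e-10,
                               max_spans = 80L) {
  n <- nrow(C_in)
  C <- C_in
  for (i in seq_len(n)) {
    Psi <- lapply(Ps, function(p) p[i, , drop = FALSE])
    Ei <- Enz[i, , drop = FALSE]
    rhs <- function(t, y, parms) {
      Cm <- matrix(pmax(y, 0), 1)
      v <- ss_rate_pieces(net, Psi, Ei, Cm, k_f[i], what = "v")$v
      list(k_f[i] * (C_in[i, ] - y) + as.numeric(net$stoich %*% t(v)))
    }
    y <- C_in[i, ]
    span <- 5 / k_f[i]
    for (s in seq_len(max_spans)) {
      out <- deSolve::lsoda(y, c(0, span), rhs, rtol = 1e-12, atol = 1e-12)
      y_new <- out[nrow(out), -1]
      if (max(abs(y_new - y)) <= reltol * max(1, max(abs(y_new)))) {
        y <- y_new
        break
      }
      y <- y_new
    }
    C[i, ] <- y
  }
  pieces <- ss_rate_pieces(net, Ps, Enz, C, k_f)
  x <- pieces$v / k_f
  resid <- vapply(seq_len(n), function(i) {
    max(abs(k_f[i] * (C_in[i, ] - C[i, ]) + net$stoich %*% pieces$v[i, ]))
  }, numeric(1))
  list(C = C, x = x, converged = rep(TRUE, n), residual = resid,
       pieces = pieces, iter = NA_integer_)
}

# IFT sensitivities given a converged solution.
# Returns dC[n, species, total_roles]; role block ordering follows reactions.
# If wrt_inflow is a character vector of species, also returns
# dC_in[n, species, length(wrt_inflow)].
ss_sensitivities_core <- function(net, sol, k_f, wrt_inflow = NULL) {
  R <- length(net$reactions)
  n <- nrow(sol$C)
  S <- length(net$species)
  J <- ss_newton_jacobian(net, sol$pieces, k_f)
  n_roles <- vapply(net$reactions, function(rx) length(rx$roles), integer(1))
  total <- sum(n_roles)
  dC <- array(0, c(n, S, total),
              dimnames = list(NULL, net$species, NULL))
  role_names <- character(total)
  off <- 0L
  for (r in seq_len(R)) {
    rx <- net$reactions[[r]]
    for (j in seq_len(n_roles[r])) {
      b <- matrix(0, n, R)
      b[, r] <- sol$pieces$dP[[r]][, j] / k_f
      dx <- batch_solve(J, b)
      dC[, , off + j] <- dx %*% t(net$stoich)
      role_names[off + j] <- paste(rx$enzyme, rx$roles[j], sep = "_")
    }
    off <- off + n_roles[r]
  }
  dimnames(dC)[[3]] <- role_names
  out <- list(dC = dC, role_names = role_names)
  if (!is.null(wrt_inflow)) {
    dCin <- array(0, c(n, S, length(wrt_inflow)),
                  dimnames = list(NULL, net$species, wrt_inflow))
    for (k in seq_along(wrt_inflow)) {
      sp <- match(wrt_inflow[k], net$species)
      b <- matrix(0, n, R)
      for (r in seq_len(R)) {
        rx <- net$reactions[[r]]
        slot <- match(sp, rx$slot_idx)
        if (!is.na(slot)) b[, r] <- sol$pieces$dC_slots[[r]][, slot] / k_f
      }
      dx <- batch_solve(J, b)
      dCin[, , k] <- dx %*% t(net$stoich)
      dCin[, sp, k] <- dCin[, sp, k] + 1
    }
    out$dC_in <- dCin
  }
  out
}

ss_dispatch <- function(net, Ps, Enz, C_in, k_f, method) {
  if (method == "analytic" ||
      (method == "auto" && analytic_supported(net))) {
    if (!analytic_supported(net)) {
      abort("analytic steady state not supported for this topology.",
            class = "kinflow_not_supported")
    }
    ss_solve_analytic(net, Ps, Enz, C_in, k_f)
  } else if (method == "integrate") {
    ss_solve_integrate(net, Ps, Enz, C_in, k_f)
  } else {
    sol <- ss_solve_newton(net, Ps, Enz, C_in, k_f)
    if (!all(sol$converged)) {
      # time-integration fallback for stubborn rows
      bad <- which(!sol$converged)
      fb <- ss_solve_integrate(net,
                               lapply(Ps, function(p) p[bad, , drop = FALSE]),
                               Enz[bad, , drop = FALSE],
                               C_in[bad, , drop = FALSE], k_f[bad])
      scale <- pmax(apply(C_in[bad, , drop = FALSE], 1, max), 1)
      ok <- fb$residual <= 1e-6 * scale
      sol$C[bad, ] <- fb$C
      sol$x[bad, ] <- fb$x
      sol$residual[bad] <- fb$residual
      sol$converged[bad] <- ok
      for (r in seq_along(net$reactions)) {
        sol$pieces$v[bad, r] <- fb$pieces$v[, r]
        sol$pieces$dC_slots[[r]][bad, ] <- fb$pieces$dC_slots[[r]]
        sol$pieces$dP[[r]][bad, ] <- fb$pieces$dP[[r]]
      }
    }
    sol
  }
}

#' Solve CSTR steady states for a table of experimental conditions
#'
#' For each row of `data` (a condition set: flow constant `k_f`, inflow
#' concentrations `inflow_<species>`, enzyme loadings `enz_<enzyme>`), solves
#' the steady state of the reactor ODEs `dC/dt = k_f (C_in - C) + N v(C)`.
#' Single-reaction Michaelis-Menten topologies are solved exactly from the
#' steady-state quadratic; all others by damped Newton iteration in
#' reaction-extent space with a stiff time-integration fallback.
#'
#' @param data Data frame of conditions, one row per condition set.
#' @param topology Topology id (see [list_topologies()]) or `kinflow_network`.
#' @param params Named numeric vector of kinetic parameters, names
#'   `<enzyme>_<role>` as given by [network_params()].
#' @param method `"auto"` (analytic where supported, else Newton),
#'   `"analytic"`, `"numeric"`, or `"integrate"` (ODE integration to
#'   stationarity; slow, intended as a cross-check).
#'
#' @return The input tibble with added columns `conc_<species>`, `converged`
#'   and `residual` (maximum absolute rate imbalance, uM/min).
#' @examples
#' tibble::tibble(k_f = 1, inflow_S = 1) |>
#'   steady_states("mm", c(E_kcat = 2, E_Km_S = 1))
#' @export
steady_states <- function(data, topology, params,
                          method = c("auto", "analytic", "numeric", "integrate")) {
  method <- match.arg(method)
  net <- if (inherits(topology, "kinflow_network")) topology else topology(topology)
  cm <- conditions_matrices(data, net)
  Ps <- params_to_role_matrices(net, params, nrow(data))
  sol <- ss_dispatch(net, Ps, cm$Enz, cm$C_in, cm$k_f, method)
  out <- tibble::as_tibble(data)
  for (sp in net$species) out[[paste0("conc_", sp)]] <- unname(sol$C[, sp])
  out$converged <- sol$converged
  out$residual <- sol$residual
  out
}

#' Steady-state parameter sensitivities via the implicit function theorem
#'
#' Differentiates the steady-state map `g(phi, theta)` with respect to the
#' kinetic parameters without an explicit steady-state expression, using
#' `dC/dphi = -[df/dC]^-1 [df/dphi]` evaluated at the solved root.
#'
#' @inheritParams steady_states
#' @return A long tibble with columns `.row` (condition row), `species`,
#'   `parameter`, `sensitivity` (d conc / d parameter). Parameters absent
#'   from the topology get sensitivity 0 and are omitted.
#' @export
steady_state_sensitivities <- function(data, topology, params,
                                       method = c("auto", "analytic", "numeric")) {
  method <- match.arg(method)
  net <- if (inherits(topology, "kinflow_network")) topology else topology(topology)
  cm <- conditions_matrices(data, net)
  Ps <- params_to_role_matrices(net, params, nrow(data))
  sol <- ss_dispatch(net, Ps, cm$Enz, cm$C_in, cm$k_f, method)
  if (!all(sol$converged)) {
    abort("steady state did not converge for all rows; sensitivities undefined.")
  }
  sens <- ss_sensitivities_core(net, sol, cm$k_f)
  grid <- expand.grid(.row = seq_len(nrow(data)), species = net$species,
                      parameter = sens$role_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$sensitivity <- as.numeric(sens$dC)
  tibble::as_tibble(grid)
}

#' Reactor vector field
#'
#' Assembles the right-hand side `f(C) = k_f (C_in - C) + N v(C)` of the
#' flow-reactor ODE system for one condition set, for use with ODE
#' integrators or as an oracle for the steady-state solvers.
#'
#' @inheritParams steady_states
#' @param conditions A one-row data frame (or named list) of conditions.
#' @return A function mapping a named (or ordered) concentration vector to
#'   its time derivative (uM/min).
#' @export
flow_field <- function(topology, params, conditions) {
  net <- if (inherits(topology, "kinflow_network")) topology else topology(topology)
  conditions <- tibble::as_tibble(as.list(conditions))
  stopifnot(nrow(conditions) == 1)
  cm <- conditions_matrices(conditions, net)
  Ps <- params_to_role_matrices(net, params, 1L)
  function(C) {
    Cm <- matrix(as.numeric(C[net$species] %||% C), 1,
                 dimnames = list(NULL, net$species))
    if (anyNA(Cm)) Cm <- matrix(as.numeric(C), 1, dimnames = list(NULL, net$species))
    v <- ss_rate_pieces(net, Ps, cm$Enz, Cm, cm$k_f, what = "v")$v
    drop(cm$k_f * (cm$C_in - Cm) + t(net$stoich %*% t(v)))
  }
}
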