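# Prior specifications and unconstrained-space transforms.
#
# Each free parameter is sampled on an unconstrained scale z:
#   log       for positive parameters (log-normal, half-normal, gamma priors)
#   identity  for normal priors
#   logit     (scaled) for uniform priors on (a, b)
# Prior log-densities are evaluated in z-space with the transform Jacobian
# included, so the sampler target is simply log prior(z) + log lik(phi(z)).

#' Prior specification row
#'
#' @param param Parameter name.
#' @param dist One of `"lognormal"` (a = meanlog, b = sdlog), `"normal"`
#'   (a = mean, b = sd), `"halfnormal"` (a = scale), `"gamma"` (a = shape,
#'   b = rate), `"uniform"` (a, b = bounds).
#' @param a,b Hyperparameters.
#' @return A one-row tibble; rows from several calls can be bound together
#'   and passed to [flow_model()].
#' @examples
#' prior_spec("E_Ki", "uniform", 1, 1e4)
#' @export
prior_spec <- function(param, dist, a, b = NA_real_) {
  dist <- match.arg(dist, c("lognormal", "normal", "halfnormal", "gamma", "uniform"))
  if (dist %in% c("lognormal", "normal", "gamma", "uniform") && is.na(b)) {
    abort(sprintf("prior '%s' needs two hyperparameters.", dist))
  }
  if (dist == "uniform" && (a >= b || a < 0)) {
    abort("uniform prior needs 0 <= a < b.")
  }
  tibble::tibble(param = param, dist = dist, a = as.numeric(a), b = as.numeric(b))
}

prior_transform <- function(dist) {
  c(lognormal = "log", halfnormal = "log", gamma = "log",
    normal = "identity", uniform = "logit")[dist]
}

# vectorized over a parameter table; returns phi, lp (sum-able), dlp/dz, dphi/dz
prior_eval_z <- function(pars, z) {
  n <- length(z)
  phi <- numeric(n); lp <- numeric(n); dlp <- numeric(n); dphi <- numeric(n)
  d <- .subset2(pars, "dist"); a <- .subset2(pars, "a"); b <- .subset2(pars, "b")
  i <- d == "lognormal"
  if (any(i)) {
    phi[i] <- exp(z[i])
    lp[i] <- stats::dnorm(z[i], a[i], b[i], log = TRUE)
    dlp[i] <- -(z[i] - a[i]) / b[i]^2
    dphi[i] <- phi[i]
  }
  i <- d == "normal"
  if (any(i)) {
    phi[i] <- z[i]
    lp[i] <- stats::dnorm(z[i], a[i], b[i], log = TRUE)
    dlp[i] <- -(z[i] - a[i]) / b[i]^2
    dphi[i] <- 1
  }
  i <- d == "halfnormal"
  if (any(i)) {
    phi[i] <- exp(z[i])
    lp[i] <- log(2) + stats::dnorm(phi[i], 0, a[i], log = TRUE) + z[i]
    dlp[i] <- 1 - phi[i]^2 / a[i]^2
    dphi[i] <- phi[i]
  }
  i <- d == "gamma"
  if (any(i)) {
    phi[i] <- exp(z[i])
    lp[i] <- stats::dgamma(phi[i], shape = a[i], rate = b[i], log = TRUE) + z[i]
    dlp[i] <- a[i] - b[i] * phi[i]
    dphi[i] <- phi[i]
  }
  i <- d == "uniform"
  if (any(i)) {
    s <- stats::plogis(z[i])
    phi[i] <- a[i] + (b[i] - a[i]) * s
    # uniform density is constant; only the logit Jacobian varies with z
    lp[i] <- log(s) + log1p(-s)
    dlp[i] <- 1 - 2 * s
    dphi[i] <- (b[i] - a[i]) * s * (1 - s)
  }
  list(phi = phi, lp = lp, dlp = dlp, dphi = dphi)
}

# z such that phi(z) is the prior median (sampling start point before jitter)
prior_median_z <- function(pars) {
  vapply(seq_len(nrow(pars)), function(i) {
    switch(pars$dist[i],
      lognormal = pars$a[i],
      normal = pars$a[i],
      halfnormal = log(pars$a[i] * stats::qnorm(0.75)),
      gamma = log(stats::qgamma(0.5, shape = pars$a[i], rate = pars$b[i])),
      uniform = 0)
  }, numeric(1))
}

phi_to_z <- function(pars, phi) {
  z <- numeric(length(phi))
  for (i in seq_along(phi)) {
    z[i] <- switch(prior_transform(pars$dist[i]),
      log = log(phi[i]),
      identity = phi[i],
      logit = stats::qlogis(pmin(pmax((phi[i] - pars$a[i]) / (pars$b[i] - pars$a[i]),
                                      1e-12), 1 - 1e-12)))
  }
  z
}
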