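# MCMC convergence diagnostics: rank-normalized split R-hat and bulk
# effective sample size, computed from an iterations x chains draw matrix.

split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Split rank-normalized R-hat
#'
#' @param x Matrix of posterior draws, iterations by chains.
#' @return The potential-scale-reduction statistic; values near 1 indicate
#'   between-chain agreement, values above ~1.01 indicate non-convergence.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(NA_real_)
  xs <- split_chains(x)
  # identical chains: rank normalization leaves no between-chain variance
  bulk <- rhat_basic(rank_normalize(xs))
  folded <- rhat_basic(rank_normalize(abs(xs - stats::median(xs))))
  max(bulk, folded)
}

ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  var_plus <- W * (n - 1) / n + if (m > 1) stats::var(means) else 0
  if (var_plus == 0) return(n * m)
  # chain-averaged autocovariances, Geyer initial monotone sequence
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = n - 1, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # pair sums, truncate at first negative, enforce monotonicity
  max_pairs <- floor((n - 1) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(p) || p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
  }
  max(n * m / tau, 1e-8)
}

#' Bulk effective sample size
#'
#' Rank-normalized effective sample size of the draws, combining
#' within-chain autocorrelation estimates across chains.
#' @inheritParams rhat
#' @return Effective number of independent draws.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  ess_basic(rank_normalize(split_chains(x)))
}

#' Convergence diagnostics for a posterior fit
#'
#' @param fit A `kinflow_fit`.
#' @return Tibble with one row per parameter: split rank-normalized `rhat`,
#'   bulk effective sample size, and the fit-wide divergence count.
#' @export
mcmc_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "kinflow_fit"))
  pn <- dimnames(fit$draws)[[3]]
  single <- dim(fit$draws)[2] < 2
  out <- purrr::map_dfr(pn, function(p) {
    x <- par_draws(fit, p)
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    tibble::tibble(parameter = p,
                   rhat = if (single) NA_real_ else rhat(x),
                   ess_bulk = ess_bulk(x))
  })
  out$divergences <- sum(fit$sampler_stats$divergent)
  out
}
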