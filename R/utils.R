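# internal helpers shared across modules

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @importFrom rlang %||% abort warn inform
NULL

# highest-density interval from draws (unimodal assumption, shortest interval)
hdi_interval <- function(x, prob = 0.94) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3) return(c(lower = x[1], upper = x[n]))
  m <- max(1L, floor(prob * n))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", name))
  }
  invisible(x)
}

assert_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be nonnegative and finite.", name))
  }
  invisible(x)
}

# central finite differences of a scalar- or vector-valued function
central_diff <- function(f, x, rel_step = 1e-6) {
  x <- as.numeric(x)
  f0 <- f(x)
  out <- matrix(NA_real_, nrow = length(f0), ncol = length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    out[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  out
}
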