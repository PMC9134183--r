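#' Kinetic parameter set for a single enzyme
#'
#' Bundles the parameters of a Michaelis-Menten-like rate law and validates
#' their domains. The maximal rate is always derived as
#' `V_max = k_cat * enzyme_conc` and never stored independently.
#'
#' @param k_cat Turnover number (per minute), strictly positive.
#' @param enzyme_conc Effective enzyme concentration (uM); for bead-loaded
#'   reactors this is proportional to the bead volume loaded. Default 1, in
#'   which case `k_cat` is interpreted as an effective maximal rate.
#' @param K_M Named numeric vector of Michaelis constants (uM), one per
#'   substrate.
#' @param K_I Inhibition constant (uM), optional.
#' @param hill_n Cooperativity exponent (dimensionless, >= 1), optional.
#'
#' @return A list of class `kinetic_params` with a derived `V_max`.
#' @examples
#' p <- kinetic_params(k_cat = 30, K_M = c(S = 200))
#' v_max(p)
#' @export
kinetic_params <- function(k_cat, enzyme_conc = 1, K_M = numeric(),
                           K_I = NULL, hill_n = NULL) {
  assert_positive(k_cat, "k_cat")
  assert_positive(enzyme_conc, "enzyme_conc")
  if (length(K_M)) assert_positive(K_M, "K_M")
  if (!is.null(K_I)) assert_positive(K_I, "K_I")
  if (!is.null(hill_n) && (!is.finite(hill_n) || hill_n < 1)) {
    abort("`hill_n` must be >= 1.")
  }
  structure(
    list(k_cat = k_cat, enzyme_conc = enzyme_conc, K_M = K_M,
         K_I = K_I, hill_n = hill_n),
    class = "kinetic_params"
  )
}

#' @rdname kinetic_params
#' @param p A `kinetic_params` object.
#' @export
v_max <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  p$k_cat * p$enzyme_conc
}

#' Michaelis-Menten rate laws
#'
#' Vectorized evaluation of the rate expressions used by the flow-reactor
#' topologies: irreversible Michaelis-Menten, its uncompetitive-inhibition
#' variant, the double-saturation bi-substrate form, and the five G6PDH
#' product-inhibition hypotheses (H0: no inhibition; H1: competitive at the
#' NAD site; H2: competitive at the G6P site; H3: noncompetitive; H4:
#' cooperative noncompetitive with Hill exponent `hill`).
#'
#' All rates are zero at zero substrate, nonnegative on the nonnegative
#' orthant, and bounded by `Vmax`.
#'
#' @param S,I,A,B,G6P,NAD,NADH Concentrations (uM), nonnegative.
#' @param Vmax Maximal rate `k_cat * [E]` (uM/min), positive.
#' @param Km,K_A,K_B,K_G6P,K_NAD Michaelis constants (uM), positive.
#' @param Ki,K_I Inhibition constant (uM), positive.
#' @param hypothesis One of `"H0"`..`"H4"`.
#' @param hill Hill exponent (>= 1), used by H4 only.
#'
#' @return Numeric vector of reaction rates (uM/min).
#' @examples
#' mm_rate(S = 400, Vmax = 10, Km = 100)   # 8
#' uncompetitive_mm_rate(S = 5, I = 2, Vmax = 10, Km = 5, Ki = 2)
#' @export
mm_rate <- function(S, Vmax, Km) {
  assert_nonnegative(S, "S"); assert_positive(Vmax, "Vmax")
  assert_positive(Km, "Km")
  Vmax * S / (Km + S)
}

#' @rdname mm_rate
#' @export
uncompetitive_mm_rate <- function(S, I, Vmax, Km, Ki) {
  assert_nonnegative(S, "S"); assert_nonnegative(I, "I")
  assert_positive(Vmax, "Vmax"); assert_positive(Km, "Km")
  assert_positive(Ki, "Ki")
  Vmax * S / (Km + S * (1 + I / Ki))
}

#' @rdname mm_rate
#' @export
bisubstrate_rate <- function(A, B, Vmax, K_A, K_B) {
  assert_nonnegative(A, "A"); assert_nonnegative(B, "B")
  assert_positive(Vmax, "Vmax"); assert_positive(K_A, "K_A")
  assert_positive(K_B, "K_B")
  Vmax * A * B / ((K_A + A) * (K_B + B))
}

#' @rdname mm_rate
#' @export
g6pdh_rate <- function(hypothesis, G6P, NAD, NADH, Vmax, K_G6P, K_NAD,
                       K_I = NULL, hill = 1) {
  hypothesis <- match.arg(hypothesis, c("H0", "H1", "H2", "H3", "H4"))
  assert_nonnegative(NADH, "NADH")
  base_args <- function(ka, kb) bisubstrate_rate(G6P, NAD, Vmax, ka, kb)
  if (hypothesis != "H0") {
    if (is.null(K_I)) abort(sprintf("hypothesis %s requires `K_I`.", hypothesis))
    assert_positive(K_I, "K_I")
  }
  if (hypothesis == "H4" && (any(!is.finite(hill)) || any(hill < 1))) {
    abort("`hill` must be >= 1 for H4.")
  }
  switch(hypothesis,
    H0 = base_args(K_G6P, K_NAD),
    H1 = Vmax * G6P * NAD / ((K_G6P + G6P) * (K_NAD * (1 + NADH / K_I) + NAD)),
    H2 = Vmax * G6P * NAD / ((K_G6P * (1 + NADH / K_I) + G6P) * (K_NAD + NAD)),
    H3 = base_args(K_G6P, K_NAD) / (1 + NADH / K_I),
    H4 = base_args(K_G6P, K_NAD) / (1 + (NADH / K_I)^hill)
  )
}

# ---------------------------------------------------------------------------
# Internal registry of vectorized rate laws with analytic derivatives.
#
# Each law operates on:
#   C : numeric matrix, one column per slot (substrates first, then modifiers)
#   P : numeric matrix, one column per role (per-row parameter values)
#   E : numeric vector, effective enzyme concentration per row
# and provides rate(), d_conc() (n x n_slots) and d_par() (n x n_roles).
# Role names carry a "{slot}" placeholder resolved at reaction construction.

law_registry <- new.env(parent = emptyenv())

register_rate_law <- function(law) {
  stopifnot(is.character(law$name), is.function(law$rate))
  assign(law$name, law, envir = law_registry)
  invisible(law$name)
}

#' Rate-law registry
#'
#' Rate laws are registered by name and referenced by reaction definitions in
#' a topology. `list_rate_laws()` names the built-in laws; `rate_law()`
#' retrieves one.
#'
#' @param name Registry key, e.g. `"mm"`, `"mm_uncompetitive"`, `"bi_mm"`,
#'   `"g6pdh_h0"` .. `"g6pdh_h4"`.
#' @return `rate_law()` returns the registry entry (a list with slot, role and
#'   derivative definitions); `list_rate_laws()` a character vector.
#' @export
rate_law <- function(name) {
  if (!exists(name, envir = law_registry, inherits = FALSE)) {
    abort(sprintf("Unknown rate law '%s'. Known: %s.",
                  name, paste(list_rate_laws(), collapse = ", ")))
  }
  get(name, envir = law_registry, inherits = FALSE)
}

#' @rdname rate_law
#' @export
list_rate_laws <- function() sort(ls(law_registry))

# -- law definitions --------------------------------------------------------

register_rate_law(list(
  name = "mm",
  substrates = "S", modifiers = character(),
  roles = c("kcat", "Km_{S}"),
  rate = function(C, P, E) {
    P[, 1] * E * C[, 1] / (P[, 2] + C[, 1])
  },
  d_conc = function(C, P, E) {
    den <- P[, 2] + C[, 1]
    cbind(P[, 1] * E * P[, 2] / den^2)
  },
  d_par = function(C, P, E) {
    den <- P[, 2] + C[, 1]
    cbind(E * C[, 1] / den, -P[, 1] * E * C[, 1] / den^2)
  }
))

register_rate_law(list(
  name = "mm_uncompetitive",
  substrates = "S", modifiers = "I",
  roles = c("kcat", "Km_{S}", "Ki"),
  rate = function(C, P, E) {
    P[, 1] * E * C[, 1] / (P[, 2] + C[, 1] * (1 + C[, 2] / P[, 3]))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    den <- P[, 2] + C[, 1] * (1 + C[, 2] / P[, 3])
    cbind(vm * P[, 2] / den^2,
          -vm * C[, 1]^2 / (P[, 3] * den^2))
  },
  d_par = function(C, P, E) {
    vm <- P[, 1] * E
    den <- P[, 2] + C[, 1] * (1 + C[, 2] / P[, 3])
    cbind(E * C[, 1] / den,
          -vm * C[, 1] / den^2,
          vm * C[, 1]^2 * C[, 2] / (P[, 3]^2 * den^2))
  }
))

register_rate_law(list(
  name = "bi_mm",
  substrates = c("A", "B"), modifiers = character(),
  roles = c("kcat", "Km_{A}", "Km_{B}"),
  rate = function(C, P, E) {
    P[, 1] * E * C[, 1] * C[, 2] / ((P[, 2] + C[, 1]) * (P[, 3] + C[, 2]))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    cbind(vm * C[, 2] * P[, 2] / (da^2 * db),
          vm * C[, 1] * P[, 3] / (da * db^2))
  },
  d_par = function(C, P, E) {
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    v <- P[, 1] * E * C[, 1] * C[, 2] / (da * db)
    cbind(E * C[, 1] * C[, 2] / (da * db), -v / da, -v / db)
  }
))

# G6PDH product-inhibition family: slots (A = G6P, B = NAD, H = NADH).
# H0 ignores H; H1/H2 scale a Michaelis constant; H3/H4 scale the whole rate.

register_rate_law(list(
  name = "g6pdh_h0",
  substrates = c("A", "B"), modifiers = "H",
  roles = c("kcat", "Km_{A}", "Km_{B}"),
  rate = function(C, P, E) {
    P[, 1] * E * C[, 1] * C[, 2] / ((P[, 2] + C[, 1]) * (P[, 3] + C[, 2]))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    cbind(vm * C[, 2] * P[, 2] / (da^2 * db),
          vm * C[, 1] * P[, 3] / (da * db^2),
          0)
  },
  d_par = function(C, P, E) {
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    v <- P[, 1] * E * C[, 1] * C[, 2] / (da * db)
    cbind(E * C[, 1] * C[, 2] / (da * db), -v / da, -v / db)
  }
))

register_rate_law(list(
  name = "g6pdh_h1",
  substrates = c("A", "B"), modifiers = "H",
  roles = c("kcat", "Km_{A}", "Km_{B}", "Ki"),
  rate = function(C, P, E) {
    m <- 1 + C[, 3] / P[, 4]
    P[, 1] * E * C[, 1] * C[, 2] / ((P[, 2] + C[, 1]) * (P[, 3] * m + C[, 2]))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    m <- 1 + C[, 3] / P[, 4]
    da <- P[, 2] + C[, 1]; db <- P[, 3] * m + C[, 2]
    v <- vm * C[, 1] * C[, 2] / (da * db)
    cbind(vm * C[, 2] * P[, 2] / (da^2 * db),
          vm * C[, 1] * (P[, 3] * m) / (da * db^2),
          -v * (P[, 3] / P[, 4]) / db)
  },
  d_par = function(C, P, E) {
    m <- 1 + C[, 3] / P[, 4]
    da <- P[, 2] + C[, 1]; db <- P[, 3] * m + C[, 2]
    v <- P[, 1] * E * C[, 1] * C[, 2] / (da * db)
    cbind(E * C[, 1] * C[, 2] / (da * db),
          -v / da,
          -v * m / db,
          v * (P[, 3] * C[, 3] / P[, 4]^2) / db)
  }
))

register_rate_law(list(
  name = "g6pdh_h2",
  substrates = c("A", "B"), modifiers = "H",
  roles = c("kcat", "Km_{A}", "Km_{B}", "Ki"),
  rate = function(C, P, E) {
    m <- 1 + C[, 3] / P[, 4]
    P[, 1] * E * C[, 1] * C[, 2] / ((P[, 2] * m + C[, 1]) * (P[, 3] + C[, 2]))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    m <- 1 + C[, 3] / P[, 4]
    da <- P[, 2] * m + C[, 1]; db <- P[, 3] + C[, 2]
    v <- vm * C[, 1] * C[, 2] / (da * db)
    cbind(vm * C[, 2] * (P[, 2] * m) / (da^2 * db),
          vm * C[, 1] * P[, 3] / (da * db^2),
          -v * (P[, 2] / P[, 4]) / da)
  },
  d_par = function(C, P, E) {
    m <- 1 + C[, 3] / P[, 4]
    da <- P[, 2] * m + C[, 1]; db <- P[, 3] + C[, 2]
    v <- P[, 1] * E * C[, 1] * C[, 2] / (da * db)
    cbind(E * C[, 1] * C[, 2] / (da * db),
          -v * m / da,
          -v / db,
          v * (P[, 2] * C[, 3] / P[, 4]^2) / da)
  }
))

register_rate_law(list(
  name = "g6pdh_h3",
  substrates = c("A", "B"), modifiers = "H",
  roles = c("kcat", "Km_{A}", "Km_{B}", "Ki"),
  rate = function(C, P, E) {
    g <- 1 / (1 + C[, 3] / P[, 4])
    g * P[, 1] * E * C[, 1] * C[, 2] / ((P[, 2] + C[, 1]) * (P[, 3] + C[, 2]))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    g <- 1 / (1 + C[, 3] / P[, 4])
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    v0 <- vm * C[, 1] * C[, 2] / (da * db)
    cbind(g * vm * C[, 2] * P[, 2] / (da^2 * db),
          g * vm * C[, 1] * P[, 3] / (da * db^2),
          -v0 * g^2 / P[, 4])
  },
  d_par = function(C, P, E) {
    g <- 1 / (1 + C[, 3] / P[, 4])
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    v0 <- P[, 1] * E * C[, 1] * C[, 2] / (da * db)
    cbind(g * E * C[, 1] * C[, 2] / (da * db),
          -g * v0 / da,
          -g * v0 / db,
          v0 * g^2 * C[, 3] / P[, 4]^2)
  }
))

register_rate_law(list(
  name = "g6pdh_h4",
  substrates = c("A", "B"), modifiers = "H",
  roles = c("kcat", "Km_{A}", "Km_{B}", "Ki", "hill"),
  rate = function(C, P, E) {
    u <- (C[, 3] / P[, 4])^P[, 5]
    P[, 1] * E * C[, 1] * C[, 2] /
      ((P[, 2] + C[, 1]) * (P[, 3] + C[, 2]) * (1 + u))
  },
  d_conc = function(C, P, E) {
    vm <- P[, 1] * E
    u <- (C[, 3] / P[, 4])^P[, 5]
    g <- 1 / (1 + u)
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    v0 <- vm * C[, 1] * C[, 2] / (da * db)
    # d u / d H = n * u / H, finite limit 0 at H = 0 for n > 1
    duH <- ifelse(C[, 3] > 0, P[, 5] * u / C[, 3],
                  ifelse(P[, 5] == 1, 1 / P[, 4], 0))
    cbind(g * vm * C[, 2] * P[, 2] / (da^2 * db),
          g * vm * C[, 1] * P[, 3] / (da * db^2),
          -v0 * g^2 * duH)
  },
  d_par = function(C, P, E) {
    u <- (C[, 3] / P[, 4])^P[, 5]
    g <- 1 / (1 + u)
    da <- P[, 2] + C[, 1]; db <- P[, 3] + C[, 2]
    v0 <- P[, 1] * E * C[, 1] * C[, 2] / (da * db)
    # d u / d n = u * log(H/Ki); u -> 0 kills the log singularity at H = 0
    dun <- ifelse(C[, 3] > 0, u * log(C[, 3] / P[, 4]), 0)
    cbind(g * E * C[, 1] * C[, 2] / (da * db),
          -g * v0 / da,
          -g * v0 / db,
          v0 * g^2 * P[, 5] * u / P[, 4],
          -v0 * g^2 * dun)
  }
))
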