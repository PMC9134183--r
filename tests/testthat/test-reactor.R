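test_that("reactor vector field matches the flow + stoichiometry structure", {
  # pure-flow limit: with a vanishing enzyme the field is k_f (C_in - C)
  ff <- flow_field("mm", c(E_kcat = 1e-12, E_Km_S = 1),
                   list(k_f = 2, inflow_S = 3))
  expect_equal(ff(c(S = 1, P = 1)), c(S = 2 * (3 - 1), P = 2 * (0 - 1)),
               tolerance = 1e-9)
  expect_equal(ff(c(S = 3, P = 0)), c(S = 0, P = 0), tolerance = 1e-9)
  # hand-evaluated single-MM field: k_f=1, Vmax=2, Km=1, S_in=1 at (1, 0)
  ff2 <- flow_field("mm", c(E_kcat = 2, E_Km_S = 1), list(k_f = 1, inflow_S = 1))
  expect_equal(ff2(c(S = 1, P = 0)), c(S = -1, P = 1))
  # 1:1 stoichiometric coupling: d(S + P)/dt = k_f (S_in + P_in - S - P)
  ff3 <- flow_field("mm", c(E_kcat = 5, E_Km_S = 50),
                    list(k_f = 0.3, inflow_S = 100))
  for (C in list(c(S = 10, P = 5), c(S = 80, P = 40))) {
    expect_equal(sum(ff3(C)), 0.3 * (100 - sum(C)), tolerance = 1e-10)
  }
})

test_that("analytic steady state solves the quadratic exactly", {
  d <- tibble::tibble(k_f = 1, inflow_S = 1)
  ss <- steady_states(d, "mm", c(E_kcat = 2, E_Km_S = 1), method = "analytic")
  expect_equal(ss$conc_S, sqrt(2) - 1, tolerance = 1e-12)
  expect_equal(ss$conc_P, 1 - (sqrt(2) - 1), tolerance = 1e-12)
  expect_lt(ss$residual, 1e-12 * 1)
  # no enzyme -> feed passes through; empty feed -> empty reactor
  expect_equal(steady_states(d, "mm", c(E_kcat = 1e-300, E_Km_S = 1))$conc_S, 1)
  d0 <- tibble::tibble(k_f = 1, inflow_S = 0)
  expect_equal(steady_states(d0, "mm", c(E_kcat = 2, E_Km_S = 1))$conc_S, 0)
  expect_equal(steady_states(d0, "mm", c(E_kcat = 2, E_Km_S = 1))$conc_P, 0)
})

test_that("numeric solver agrees with the analytic root over many random draws", {
  set.seed(10)
  n <- 1000
  d <- tibble::tibble(k_f = runif_log(n, 0.01, 10),
                      inflow_S = runif_log(n, 1, 5000),
                      inflow_I = c(rep(0, n / 2), runif_log(n / 2, 1, 3000)))
  for (i in seq_len(4)) {  # several parameter sets across the magnitude range
    p <- c(E_kcat = runif_log(1, 0.5, 100), E_Km_S = runif_log(1, 5, 2000),
           E_Ki = runif_log(1, 50, 5000))
    a <- steady_states(d, "mm_uncompetitive", p, method = "analytic")
    b <- steady_states(d, "mm_uncompetitive", p, method = "numeric")
    expect_true(all(b$converged))
    # agreement to 1e-8 relative to the feed scale of each condition
    expect_lt(max(abs(a$conc_S - b$conc_S) / d$inflow_S), 1e-8)
    expect_lt(max(abs(a$conc_P - b$conc_P) / d$inflow_S), 1e-8)
  }
})

test_that("steady states respect conservation, washout and full-conversion limits", {
  p <- c(E_kcat = 20, E_Km_S = 100)
  # washout: k_f -> large leaves the feed unconverted
  d_hi <- tibble::tibble(k_f = 1e6, inflow_S = 500)
  ss <- steady_states(d_hi, "mm", p)
  expect_equal(ss$conc_S, 500, tolerance = 1e-3)
  # k_f -> 0 gives full conversion for irreversible MM
  d_lo <- tibble::tibble(k_f = 1e-6, inflow_S = 500)
  ss <- steady_states(d_lo, "mm", p)
  expect_equal(ss$conc_P, 500, tolerance = 1e-2)
  # conservation + monotonicity over a grid
  d <- tidyr::expand_grid(k_f = c(0.05, 0.2, 1, 5), inflow_S = c(10, 100, 1000))
  ss <- steady_states(d, "mm", p)
  expect_equal(ss$conc_S + ss$conc_P, ss$inflow_S, tolerance = 1e-8)
  by_kf <- dplyr::arrange(ss, inflow_S, k_f)
  for (s_in in unique(by_kf$inflow_S)) {
    pp <- by_kf$conc_P[by_kf$inflow_S == s_in]
    expect_true(all(diff(pp) <= 1e-10))  # [P]_ss nonincreasing in k_f
  }
  by_sin <- dplyr::arrange(ss, k_f, inflow_S)
  for (kf in unique(by_sin$k_f)) {
    pp <- by_sin$conc_P[by_sin$k_f == kf]
    expect_true(all(diff(pp) >= -1e-10))  # nondecreasing in S_in
  }
})

test_that("GDH+HK network matches stiff time integration", {
  set.seed(11)
  p <- c(GDH_kcat = 20, GDH_Km_Glc = 300, GDH_Km_NAD = 150,
         HK_kcat = 25, HK_Km_Glc = 120, HK_Km_ATP = 400)
  d <- tibble::tibble(k_f = c(0.05, 0.1, 0.3),
                      inflow_Glc = c(1000, 2500, 800),
                      inflow_NAD = c(300, 700, 150),
                      inflow_ATP = c(600, 400, 900))
  newton <- steady_states(d, "gdh_hk", p, method = "numeric")
  integ <- steady_states(d, "gdh_hk", p, method = "integrate")
  for (sp in topology("gdh_hk")$species) {
    col <- paste0("conc_", sp)
    expect_equal(newton[[col]], integ[[col]], tolerance = 1e-6)
  }
  # glucose is shared: total carbon and cofactor pools balance
  expect_equal(newton$conc_Glc + newton$conc_GDL + newton$conc_G6P,
               newton$inflow_Glc, tolerance = 1e-8)
  expect_equal(newton$conc_NAD + newton$conc_NADH, newton$inflow_NAD,
               tolerance = 1e-8)
})

test_that("IFT sensitivities match central finite differences on every topology", {
  set.seed(12)
  cases <- list(
    list(top = "mm", d = tibble::tibble(k_f = 0.2, inflow_S = 400),
         p = c(E_kcat = 15, E_Km_S = 120)),
    list(top = "mm_uncompetitive",
         d = tibble::tibble(k_f = 0.1, inflow_S = 500, inflow_I = 800),
         p = c(E_kcat = 30, E_Km_S = 200, E_Ki = 1000)),
    list(top = "gdh",
         d = tibble::tibble(k_f = 0.1, inflow_Glc = 1500, inflow_NAD = 400),
         p = c(GDH_kcat = 20, GDH_Km_Glc = 300, GDH_Km_NAD = 150)),
    list(top = "gdh_hk",
         d = tibble::tibble(k_f = 0.1, inflow_Glc = 1500, inflow_NAD = 400,
                            inflow_ATP = 700),
         p = c(GDH_kcat = 20, GDH_Km_Glc = 300, GDH_Km_NAD = 150,
               HK_kcat = 25, HK_Km_Glc = 120, HK_Km_ATP = 400)),
    list(top = "g6pdh_h4",
         d = tibble::tibble(k_f = 0.05, inflow_G6P = 600, inflow_NAD = 500),
         p = c(G6PDH_kcat = 40, G6PDH_Km_G6P = 250, G6PDH_Km_NAD = 100,
               G6PDH_Ki = 100, G6PDH_hill = 2))
  )
  for (cs in cases) {
    sens <- steady_state_sensitivities(cs$d, cs$top, cs$p)
    for (pn in names(cs$p)) {
      f <- function(v) {
        pp <- cs$p; pp[pn] <- v
        ss <- steady_states(cs$d, cs$top, pp, method = "numeric")
        unlist(ss[paste0("conc_", topology(cs$top)$species)])
      }
      h <- 1e-6 * cs$p[[pn]]
      fd <- (f(cs$p[[pn]] + h) - f(cs$p[[pn]] - h)) / (2 * h)
      got <- sens$sensitivity[sens$parameter == pn]
      expect_equal(got, unname(fd), tolerance = 1e-4,
                   info = paste(cs$top, pn))
    }
  }
})

test_that("scalar implicit-function-theorem value and absent parameters", {
  d <- tibble::tibble(k_f = 1, inflow_S = 1)
  s <- steady_state_sensitivities(d, "mm", c(E_kcat = 2, E_Km_S = 1))
  expect_equal(s$sensitivity[s$species == "S" & s$parameter == "E_kcat"],
               -0.146447, tolerance = 1e-5)
  # a parameter not in the topology never appears in the sensitivity table
  s2 <- steady_state_sensitivities(d, "mm",
                                   c(E_kcat = 2, E_Km_S = 1, E_Ki = 1000))
  expect_false("E_Ki" %in% s2$parameter)
})

test_that("analytic method refuses unsupported topologies; solver flags failures", {
  d <- tibble::tibble(k_f = 0.1, inflow_Glc = 100, inflow_NAD = 100)
  expect_error(
    steady_states(d, "gdh", c(GDH_kcat = 1, GDH_Km_Glc = 1, GDH_Km_NAD = 1),
                  method = "analytic"),
    class = "kinflow_not_supported")
  expect_error(steady_states(tibble::tibble(inflow_S = 1), "mm",
                             c(E_kcat = 1, E_Km_S = 1)), "k_f")
})
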