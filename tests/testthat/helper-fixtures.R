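# Shared fixtures for the test suite. Expensive posterior fits are computed
# once per session and reused across test files; every fixture has a fixed
# seed so the suite is reproducible.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

quiet_model <- function(...) {
  suppressMessages(suppressWarnings(flow_model(..., quiet = TRUE)))
}

# random positive parameter draws for property tests
runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# --- trypsin campaign (uncompetitive inhibition, two experiments) ----------

trypsin_observations <- function() fixture("tryp_obs", {
  generate_observations(scenario_trypsin(), seed = 2024)
})

trypsin_fit_combined <- function() fixture("tryp_fit_combined", {
  m <- quiet_model(trypsin_observations(),
                   parameter_map = scenario_trypsin()$parameter_map)
  sample_posterior(m, chains = 4, warmup = 500, draws = 1000, seed = 11)
})

trypsin_fit_single <- function(which) fixture(paste0("tryp_fit_", which), {
  obs <- dplyr::filter(trypsin_observations(), .data$experiment_id == which)
  m <- quiet_model(obs)
  suppressWarnings(sample_posterior(m, chains = 2, warmup = 400, draws = 800,
                                    seed = 12, check_gradient = FALSE))
})

# --- GDH/HK panel (three topologies, two batches, one corrupted exp) -------

gdhhk_observations <- function() fixture("gdhhk_obs", {
  generate_observations(scenario_gdh_hk(), seed = 77)
})

gdhhk_fit <- function(subset) fixture(paste0("gdhhk_fit_", subset), {
  sc <- scenario_gdh_hk()
  obs <- gdhhk_observations()
  keep <- scenario_truth(obs)$subsets[[subset]]
  obs_k <- dplyr::filter(obs, .data$experiment_id %in% keep)
  m <- quiet_model(obs_k, parameter_map = sc$parameter_map)
  # the small-panel fits get more chains/draws: the data-growth comparison
  # needs posterior sds with small Monte-Carlo error
  ch <- if (subset == "n16") 2 else 3
  dr <- if (subset == "n16") 500 else 350
  suppressWarnings(sample_posterior(m, chains = ch, warmup = 250, draws = dr,
                                    seed = 21, check_gradient = FALSE))
})

# --- G6PDH hypothesis machinery -------------------------------------------

fit_g6pdh_hypothesis <- function(h, obs, seed, warmup = 100, draws = 150) {
  o <- obs
  o$topology_id <- paste0("g6pdh_", tolower(h))
  m <- quiet_model(o)
  sample_posterior(m, chains = 2, warmup = warmup, draws = draws, seed = seed,
                   check_gradient = FALSE, target_accept = 0.8,
                   max_treedepth = 5)
}

compare_g6pdh_once <- function(gen_hypothesis, seed) {
  obs <- generate_observations(scenario_g6pdh(gen_hypothesis), seed = seed)
  loos <- list()
  for (h in c("H0", "H1", "H2", "H3", "H4")) {
    f <- fit_g6pdh_hypothesis(h, obs, seed = seed)
    loos[[h]] <- loo_elpd(f)
  }
  compare_models(loos)
}

# 20-replicate mechanism-recovery study under H3 (shared by acceptance tests)
g6pdh_h3_study <- function() fixture("g6pdh_h3_study", {
  lapply(1:20, function(r) compare_g6pdh_once("H3", seed = 3000 + r))
})

# parameter-recovery study: repeated reduced-size trypsin fits
recovery_study <- function(n_rep = 30) fixture("recovery_study", {
  sc <- scenario_trypsin(s_in = c(100, 300, 1000, 2000), replicates = 2)
  truth <- sc$truth
  purrr::map_dfr(seq_len(n_rep), function(r) {
    obs <- generate_observations(sc, seed = 5000 + r)
    m <- quiet_model(obs, parameter_map = sc$parameter_map)
    f <- suppressWarnings(sample_posterior(m, chains = 2, warmup = 120,
                          draws = 220, seed = 5000 + r, check_gradient = FALSE,
                          target_accept = 0.85, max_treedepth = 7))
    dr <- kinflow:::flat_draws(f)
    purrr::map_dfr(names(truth), function(p) {
      q <- stats::quantile(dr[, p], c(0.025, 0.975))
      tibble::tibble(rep = r, parameter = p, true_value = truth[[p]],
                     covered = truth[[p]] >= q[1] & truth[[p]] <= q[2])
    })
  })
})
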