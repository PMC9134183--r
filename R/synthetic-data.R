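# Synthetic steady-state campaigns with known ground truth, emulating the
# statistical structure of the three experimental designs the package
# targets: trypsin with/without an uncompetitive inhibitor, a heterogeneous
# GDH/HK reactor panel with two enzyme batches and a partially observed
# combined topology, and G6PDH under five product-inhibition mechanisms.

new_scenario <- function(name, conditions, truth, sigma, parameter_map,
                         corrupt = NULL, subsets = NULL, hypothesis = NULL) {
  structure(
    list(name = name, conditions = tibble::as_tibble(conditions),
         truth = truth, sigma = sigma, parameter_map = parameter_map,
         corrupt = corrupt %||% stats::setNames(numeric(0), character(0)),
         subsets = subsets, hypothesis = hypothesis),
    class = "kinflow_scenario"
  )
}

#' @export
print.kinflow_scenario <- function(x, ...) {
  cat("<kinflow_scenario> ", x$name, "\n", sep = "")
  cat(sprintf("  %d experiments, %d observation rows\n",
              length(unique(x$conditions$experiment_id)), nrow(x$conditions)))
  if (length(x$corrupt)) {
    cat("  corrupted:", paste(sprintf("%s (x%g)", names(x$corrupt), x$corrupt),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Trypsin inhibition scenario
#'
#' Two experiments on the `mm_uncompetitive` topology: substrate cleavage
#' without inhibitor (`inflow_I = 0`) and with the uncompetitive inhibitor
#' present. The inhibitor-free experiment identifies the turnover number and
#' Michaelis constant but carries no information on the inhibition constant.
#'
#' @param s_in Substrate inflow grid (uM).
#' @param inhibitor_in Inhibitor inflow of the second experiment (uM).
#' @param k_f Flow constant (1/min).
#' @param replicates Replicates per grid point.
#' @param sigma Observation noise SD (uM), shared by both experiments.
#' @param truth Named true parameters.
#' @return A `kinflow_scenario` for [generate_observations()].
#' @export
scenario_trypsin <- function(s_in = c(50, 100, 250, 500, 1000, 2000),
                             inhibitor_in = 1000, k_f = 0.1, replicates = 3,
                             sigma = 3,
                             truth = c(E_kcat = 30, E_Km_S = 200, E_Ki = 1000)) {
  grid <- function(exp_id, i_in) {
    tidyr::expand_grid(inflow_S = s_in, replicate = seq_len(replicates)) |>
      dplyr::mutate(experiment_id = exp_id, topology_id = "mm_uncompetitive",
                    k_f = k_f, inflow_I = i_in, observed_species = "P")
  }
  conditions <- dplyr::bind_rows(grid("tryp_no_inh", 0),
                                 grid("tryp_with_inh", inhibitor_in))
  map <- default_parameter_map(conditions)
  new_scenario("trypsin_inhibition", conditions, truth,
               sigma = c(tryp_no_inh = sigma, tryp_with_inh = sigma),
               parameter_map = map)
}

#' GDH / HK reactor panel scenario
#'
#' Sixteen experiments across three topologies: glucose-dehydrogenase
#' reactors with two enzyme batches (distinct effective turnover numbers,
#' shared Michaelis constants), hexokinase reactors, and combined GDH+HK
#' reactors in which only NADH is observed. One hexokinase experiment is
#' corrupted with inflated noise to emulate an experiment containing an
#' unknown error. `subsets` gives nested experiment sets of size 4, 6 and 16
#' for data-growth studies.
#'
#' @param replicates Replicates per grid point.
#' @param sigma Observation noise SD (uM) of clean experiments.
#' @param corrupt_factor Noise inflation of the corrupted experiment
#'   (`hk_3`); set to 1 for an all-clean panel.
#' @param truth Named true parameters (`GDH_kcat_b1`, `GDH_kcat_b2` are the
#'   batch-specific turnover numbers).
#' @return A `kinflow_scenario`.
#' @export
scenario_gdh_hk <- function(replicates = 3, sigma = 15, corrupt_factor = 10,
                            truth = c(GDH_kcat_b1 = 20, GDH_kcat_b2 = 45,
                                      GDH_Km_Glc = 300, GDH_Km_NAD = 150,
                                      HK_kcat = 25, HK_Km_Glc = 120,
                                      HK_Km_ATP = 400)) {
  gdh_exp <- function(exp_id, enz, k_f) {
    tidyr::expand_grid(inflow_Glc = c(1000, 3000), inflow_NAD = c(300, 800),
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(experiment_id = exp_id, topology_id = "gdh", k_f = k_f,
                    enz_GDH = enz, observed_species = "NADH")
  }
  hk_exp <- function(exp_id, enz, k_f) {
    tidyr::expand_grid(inflow_Glc = c(500, 2000), inflow_ATP = c(400, 1000),
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(experiment_id = exp_id, topology_id = "hk", k_f = k_f,
                    enz_HK = enz, observed_species = "ADP")
  }
  ghk_exp <- function(exp_id, enz_g, enz_h, k_f) {
    tidyr::expand_grid(inflow_Glc = c(1000, 3000), inflow_NAD = c(300, 800),
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(experiment_id = exp_id, topology_id = "gdh_hk", k_f = k_f,
                    inflow_ATP = 600, enz_GDH = enz_g, enz_HK = enz_h,
                    observed_species = "NADH")
  }
  conditions <- dplyr::bind_rows(
    gdh_exp("gdh_b1_1", 1.0, 0.10), gdh_exp("gdh_b1_2", 0.8, 0.10),
    gdh_exp("gdh_b1_3", 1.2, 0.05),
    gdh_exp("gdh_b2_1", 1.0, 0.10), gdh_exp("gdh_b2_2", 0.7, 0.20),
    gdh_exp("gdh_b2_3", 1.4, 0.10),
    hk_exp("hk_1", 1.0, 0.10), hk_exp("hk_2", 0.8, 0.05),
    hk_exp("hk_3", 1.2, 0.10), hk_exp("hk_4", 1.5, 0.20),
    hk_exp("hk_5", 0.7, 0.10),
    ghk_exp("ghk_1", 1.0, 1.0, 0.10), ghk_exp("ghk_2", 0.8, 1.2, 0.10),
    ghk_exp("ghk_3", 1.2, 0.8, 0.05), ghk_exp("ghk_4", 1.0, 1.0, 0.20),
    ghk_exp("ghk_5", 1.4, 0.7, 0.10))

  exps <- unique(conditions$experiment_id)
  # shared Km bindings plus batch-specific turnover numbers for GDH beads;
  # the combined reactors use batch-1 beads
  gdh_batch <- function(eid) if (grepl("^gdh_b2", eid)) "GDH_kcat_b2" else "GDH_kcat_b1"
  map <- dplyr::bind_rows(
    tibble::tibble(topology_id = "gdh", enzyme = "GDH", role = "kcat",
                   param = vapply(grep("^gdh_", exps, value = TRUE), gdh_batch, ""),
                   experiment_id = grep("^gdh_", exps, value = TRUE)),
    tibble::tibble(topology_id = "gdh", enzyme = "GDH",
                   role = c("Km_Glc", "Km_NAD"),
                   param = c("GDH_Km_Glc", "GDH_Km_NAD"),
                   experiment_id = NA_character_),
    tibble::tibble(topology_id = "hk", enzyme = "HK",
                   role = c("kcat", "Km_Glc", "Km_ATP"),
                   param = c("HK_kcat", "HK_Km_Glc", "HK_Km_ATP"),
                   experiment_id = NA_character_),
    tibble::tibble(topology_id = "gdh_hk", enzyme = "GDH",
                   role = c("kcat", "Km_Glc", "Km_NAD"),
                   param = c("GDH_kcat_b1", "GDH_Km_Glc", "GDH_Km_NAD"),
                   experiment_id = NA_character_),
    tibble::tibble(topology_id = "gdh_hk", enzyme = "HK",
                   role = c("kcat", "Km_Glc", "Km_ATP"),
                   param = c("HK_kcat", "HK_Km_Glc", "HK_Km_ATP"),
                   experiment_id = NA_character_))

  corrupt <- if (corrupt_factor != 1) c(hk_3 = corrupt_factor)
  new_scenario("gdh_hk_panel", conditions, truth,
               sigma = stats::setNames(rep(sigma, length(exps)), exps),
               parameter_map = map, corrupt = corrupt,
               subsets = list(n4 = c("gdh_b1_1", "gdh_b2_1", "hk_1", "ghk_1"),
                              n6 = c("gdh_b1_1", "gdh_b2_1", "hk_1", "ghk_1",
                                     "gdh_b1_2", "hk_2"),
                              n16 = exps))
}

#' G6PDH product-inhibition scenario
#'
#' Two experiments over a G6P-by-NAD inflow grid in triplicate, generated
#' under one of the five mechanism hypotheses. H0 has no inhibition
#' constant; H4 additionally carries a Hill exponent.
#'
#' @param hypothesis Generating mechanism, `"H0"` .. `"H4"`.
#' @param g6p_in,nad_in Inflow grids (uM).
#' @param replicates Replicates per grid point.
#' @param sigma Observation noise SD (uM).
#' @param kcat,km_g6p,km_nad,ki,hill True parameter values; `ki` is ignored
#'   for H0 and `hill` is only used by H4.
#' @return A `kinflow_scenario`.
#' @export
scenario_g6pdh <- function(hypothesis = c("H3", "H0", "H1", "H2", "H4"),
                           g6p_in = c(200, 600, 1800), nad_in = c(150, 600),
                           replicates = 3, sigma = 5,
                           kcat = 40, km_g6p = 250, km_nad = 100,
                           ki = 100, hill = 2) {
  hypothesis <- match.arg(hypothesis)
  tid <- paste0("g6pdh_", tolower(hypothesis))
  grid <- function(exp_id, enz, k_f) {
    tidyr::expand_grid(inflow_G6P = g6p_in, inflow_NAD = nad_in,
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(experiment_id = exp_id, topology_id = tid, k_f = k_f,
                    enz_G6PDH = enz, observed_species = "NADH")
  }
  # one high-conversion reactor (long residence time: product accumulates,
  # probing the inhibition regime) and one low-conversion reactor (short
  # residence time, low loading: pins the uninhibited kinetics)
  conditions <- dplyr::bind_rows(grid("g6pdh_1", 1.0, 0.05),
                                 grid("g6pdh_2", 0.5, 0.25))
  truth <- c(G6PDH_kcat = kcat, G6PDH_Km_G6P = km_g6p, G6PDH_Km_NAD = km_nad)
  if (hypothesis != "H0") truth <- c(truth, G6PDH_Ki = ki)
  if (hypothesis == "H4") truth <- c(truth, G6PDH_hill = hill)
  new_scenario("g6pdh_inhibition", conditions, truth,
               sigma = c(g6pdh_1 = sigma, g6pdh_2 = sigma),
               parameter_map = default_parameter_map(conditions),
               hypothesis = hypothesis)
}

#' Generate a synthetic observation table from a scenario
#'
#' Solves the steady state of every condition under the scenario's true
#' parameters and adds Gaussian observation noise (per-experiment SD,
#' inflated for corrupted experiments). Negative noisy values are resampled
#' rather than truncated, so the Gaussian observation model remains
#' well-specified.
#'
#' @param scenario A `kinflow_scenario`.
#' @param seed Integer seed; fixed seeds regenerate the identical table.
#' @return Observation tibble ready for [flow_model()], with the ground
#'   truth attached as attribute `"truth"` (see [scenario_truth()]).
#' @export
generate_observations <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "kinflow_scenario"))
  obs <- scenario$conditions
  obs$value <- 0
  template <- suppressMessages(suppressWarnings(
    flow_model(obs, parameter_map = scenario$parameter_map, quiet = TRUE)))
  phi <- numeric(nrow(template$pars))
  names(phi) <- template$pars$param
  phi[names(scenario$truth)] <- scenario$truth
  phi[template$pars$kind == "sigma"] <- 1  # unused by the deterministic map
  pred <- model_predict(template, phi)
  if (anyNA(pred)) abort("steady-state solve failed for some scenario conditions.")
  sig_eff <- scenario$sigma
  for (e in names(scenario$corrupt)) {
    sig_eff[e] <- sig_eff[e] * scenario$corrupt[e]
  }
  set.seed(as.integer(seed))
  sd_row <- sig_eff[obs$experiment_id]
  value <- pred + stats::rnorm(nrow(obs), 0, sd_row)
  bad <- which(value < 0)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    tries <- tries + 1L
    value[bad] <- pred[bad] + stats::rnorm(length(bad), 0, sd_row[bad])
    bad <- which(value < 0)
  }
  value[value < 0] <- 0
  obs$value <- value
  attr(obs, "truth") <- list(
    scenario = scenario$name, hypothesis = scenario$hypothesis,
    params = scenario$truth, sigma = sig_eff,
    corrupt = scenario$corrupt, seed = seed,
    parameter_map = scenario$parameter_map, subsets = scenario$subsets,
    steady_state = pred)
  obs
}

#' @rdname generate_observations
#' @param observations A table produced by `generate_observations()`.
#' @return `scenario_truth()` returns the ground-truth record (parameters,
#'   per-experiment noise SDs, seed).
#' @export
scenario_truth <- function(observations) {
  tr <- attr(observations, "truth")
  if (is.null(tr)) abort("no ground-truth record attached to this table.")
  tr
}

#' Read and write observation tables
#'
#' Plain comma-separated files with a header row: `experiment_id`,
#' `topology_id`, `k_f`, `inflow_<species>` columns, `enz_<enzyme>` columns,
#' `observed_species`, `value`, `replicate`. `write_observations()` also
#' writes the ground-truth sidecar `<path>.truth.json` when present.
#'
#' @param observations Observation tibble.
#' @param path File path of the CSV.
#' @return `read_observations()` returns a validated tibble.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  tr <- attr(observations, "truth")
  if (!is.null(tr)) {
    tr$parameter_map <- NULL
    # named vectors serialize as JSON objects so names survive the round trip
    tr$params <- as.list(tr$params)
    tr$sigma <- as.list(tr$sigma)
    if (length(tr$corrupt)) tr$corrupt <- as.list(tr$corrupt)
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(df)
}
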