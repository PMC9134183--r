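# kinflow

Bayesian inference of enzyme kinetics in flow reactors.

## The problem

Enzymes immobilized in polyacrylamide beads and held in a continuously
stirred tank reactor (CSTR) convert a fed substrate until inflow, outflow
and reaction balance. The steady-state outflow concentrations measured
across flow rates, feed concentrations and bead loadings carry the kinetic
information — but each experiment alone is noisy, partially observed and
often insufficient to pin every parameter. kinflow is for experimentalists
building such enzymatic reactors who want to (i) infer kinetic parameters
jointly from heterogeneous experiments, (ii) let the data rank outlier
experiments instead of hand-curating them, and (iii) decide between
competing reaction mechanisms on predictive grounds.

## The model

For species concentrations `C` (uM) in a reactor with flow constant `k_f`
(1/min), stoichiometry `N` and Michaelis–Menten-like rates `v`:

    dC/dt = k_f (C_in − C) + N v(C, phi),      V_max = k_cat [E]

Measurements at steady state (`dC/dt = 0`) give the data; each observed
concentration `y` contributes a Gaussian likelihood term
`N(y | g_species(phi, theta), sigma_e)` with the steady-state map `g`
solved exactly (single-substrate topologies) or by damped Newton iteration
in reaction-extent space. Posteriors over all kinetic parameters and one
noise parameter per experiment are sampled with a No-U-Turn sampler whose
gradients flow through the steady state via the implicit function theorem:

    dg/dphi = −[df/dC]⁻¹ [df/dphi]

Mechanism hypotheses (e.g. five NADH-product-inhibition variants of
glucose-6-phosphate dehydrogenase) are ranked by PSIS-LOO cross-validation
with exact leave-one-out refits wherever the Pareto-tail diagnostic
(k̂ > 0.7) invalidates the importance-sampling approximation.

## Worked example

Simulate the two-experiment trypsin campaign (substrate cleavage with and
without an uncompetitive inhibitor), fit the joint model, and look at the
posterior:

```r
library(kinflow)

scenario <- scenario_trypsin()          # truth: k_cat 30, K_M 200, K_I 1000
obs <- generate_observations(scenario, seed = 1)

fit <- obs |>
  flow_model(parameter_map = scenario$parameter_map, quiet = TRUE) |>
  sample_posterior(chains = 2, warmup = 300, draws = 500, seed = 1)

tidy(fit)
```

```
# A tibble: 5 x 7
  term                estimate std.error conf.low conf.high  rhat ess_bulk
  <chr>                  <dbl>     <dbl>    <dbl>     <dbl> <dbl>    <dbl>
1 E_kcat                 29.9      0.229    29.4      30.3  1.00      488.
2 E_Km_S                195.       5.63    184.      205.   1.00      424.
3 E_Ki                  995.      20.4     955.     1032.   1.01      616.
4 sigma_tryp_no_inh       3.07     0.597     2.12      4.26 1.01      484.
5 sigma_tryp_with_inh     2.86     0.515     1.99      3.83 0.999     508.
```

The inhibitor-free experiment alone identifies `k_cat` and `K_M` but not
`K_I` (its posterior reproduces the uniform prior); the inhibitor-present
experiment couples `k_cat` and `K_I` along a ridge; the joint fit collapses
the ridge, recovering all three generating values — here within two
posterior standard deviations — and estimates each experiment's noise level
(`sigma_*`, truth 3 uM) alongside.

Rank competing product-inhibition mechanisms for a G6PDH reactor:

```r
obs <- generate_observations(scenario_g6pdh("H3"), seed = 1)
loos <- lapply(c(H0 = "H0", H1 = "H1", H2 = "H2", H3 = "H3", H4 = "H4"),
               function(h) {
  o <- obs
  o$topology_id <- paste0("g6pdh_", tolower(h))
  o |>
    flow_model(quiet = TRUE) |>
    sample_posterior(chains = 2, warmup = 150, draws = 250, seed = 1,
                     target_accept = 0.85, max_treedepth = 6) |>
    loo_elpd()
})
compare_models(loos)
```

```
Model comparison by PSIS-LOO (higher elpd = more predictive power)
 rank model elpd_loo se_elpd elpd_diff se_diff
    1    H3   -110.8   4.224      0.00   0.000
    2    H4   -130.0   3.986    -19.21   5.065
    3    H0   -130.5   3.951    -19.73   5.117
    4    H1   -131.0   4.014    -20.18   5.010
    5    H2   -131.5   3.882    -20.74   4.895
```

The generating mechanism (noncompetitive inhibition, H3) tops the table and
the competitive variants trail by far more than twice the standard error of
the difference — they can be ruled out; higher elpd means more predictive
power.

Other entry points: `steady_states()` and `steady_state_sensitivities()`
for the reactor layer; `posterior_predictive()` and
`flag_outlier_experiments()` for experiment QC; `autoplot()`,
`plot_pairs()`, `plot_posterior_predictive()` for figures;
`inst/cli/kinflow.R` for a `simulate` / `fit` / `compare` command line.
The methods vignette (`vignettes/kinflow-methods.Rmd`) documents the model,
priors, solver and study designs.

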