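---
title: "Inferring enzyme kinetics in flow reactors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring enzyme kinetics in flow reactors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kinflow infers Michaelis–Menten-like kinetic parameters of enzymes
immobilized in hydrogel beads inside continuously stirred tank reactors
(CSTRs), from steady-state outflow concentrations. This vignette describes
the model, the numerical machinery, the synthetic campaigns used for
validation, and the design choices a user or maintainer should know about.

## The reactor model

A CSTR holding bead-immobilized enzymes and fed at flow constant $k_f$
(units min$^{-1}$; the inverse mean residence time) obeys, per species
concentration vector $C$ (µM),

$$\frac{dC}{dt} = k_f\,(C_\mathrm{in} - C) + N\,v(C,\phi),$$

where $N$ is the species-by-reaction stoichiometry matrix and $v$ the
vector of enzymatic rates. Rates follow Michaelis–Menten-like laws with
$V_\max = k_\mathrm{cat}\,[E]$; the effective enzyme concentration $[E]$ is
proportional to the bead volume loaded and enters through the `enz_<enzyme>`
condition column. The built-in laws are:

* `mm`: $v = V_\max S/(K_M + S)$;
* `mm_uncompetitive`: $v = V_\max S / (K_M + S\,(1 + I/K_I))$ — the
  inhibitor binds the enzyme–substrate complex. The inhibitor is modeled as
  chemically unconsumed, so its reactor concentration equals its inflow
  concentration;
* `bi_mm`: the double-saturation product form
  $v = V_\max A B / ((K_A + A)(K_B + B))$. This is the simplest
  Michaelis–Menten-like two-substrate generalization; it sits behind the
  rate-law registry so a different two-substrate mechanism can be swapped in
  without touching the reactor or inference layers;
* `g6pdh_h0` … `g6pdh_h4`: the bi-substrate law with five product-inhibition
  variants for NADH — none (H0), competitive at the NAD site
  ($K_\mathrm{NAD}\,(1 + \mathrm{NADH}/K_I)$, H1), competitive at the G6P
  site (H2), noncompetitive ($v \cdot 1/(1+\mathrm{NADH}/K_I)$, H3), and
  cooperative noncompetitive ($v \cdot 1/(1+(\mathrm{NADH}/K_I)^n)$ with
  Hill exponent $n \ge 1$, H4). At $\mathrm{NADH}=0$ all five coincide, and
  H4 with $n = 1$ equals H3.

Units are µM for concentrations, minutes for time throughout.

## Steady states and their sensitivities

Measurements are taken at steady state, $f(C, \phi, \theta) = 0$. Two
solution paths exist:

* **Closed form** for single-substrate MM topologies (with or without the
  unconsumed inhibitor): the steady state satisfies a quadratic in
  $[S]_\mathrm{ss}$ whose nonnegative branch is selected via the
  numerically stable form of the quadratic formula. Because the product of
  the two roots is $\le 0$, exactly one root lies in $[0, S_\mathrm{in}]$
  — the monostability the closed form relies on.
* **Damped Newton in reaction-extent space** otherwise. Writing
  $x_r = v_r/k_f$, the fixed point satisfies $C = C_\mathrm{in} + N x$ and
  $g(x) = x - v(C_\mathrm{in} + Nx)/k_f = 0$, with one unknown per
  reaction (one or two for all built-in topologies). This formulation keeps
  the stoichiometric conservation laws exact by construction, guarantees
  nonnegative concentrations through per-row step damping against the
  feasible box, and solves all condition sets of a topology simultaneously
  as independent rows — which is what makes gradient-based sampling
  affordable. For the laws used here $\partial v_r/\partial x_r \le 0$, so
  the Newton matrix $I - (1/k_f)\,\partial v/\partial C\, N$ has a
  unit-dominant diagonal and the iteration is robust; rows that still fail
  fall back to stiff time integration (`deSolve::lsoda`). Convergence is
  declared at $|g| \le 10^{-12}(1 + \mathrm{scale})$ with scale the largest
  inflow of the row; non-convergence is flagged, and during sampling maps
  to a rejected proposal.

Parameter sensitivities come from the implicit function theorem: at the
root, $\partial x/\partial\phi = J^{-1}\,(1/k_f)\,\partial v/\partial\phi$
and $\partial C/\partial\phi = N\,\partial x/\partial\phi$, with all
rate-law derivatives analytic. The same machinery provides derivatives with
respect to inflow concentrations, which is what allows a condition to be
promoted to a free parameter with an informed prior.

## The joint probabilistic model

Each observed steady-state concentration $y$ contributes a Gaussian term
$\mathcal{N}(y \mid g_\mathrm{species}(\phi, \theta), \sigma_e)$, with one
noise parameter $\sigma_e$ per experiment shared by its replicates. Species
a detector cannot see contribute nothing — the combined GDH+HK reactor, in
which only NADH is measured, still constrains the hexokinase parameters
through the shared glucose pool. A parameter map binds each reaction role
(turnover number, Michaelis constants, inhibition constant, Hill exponent)
to a global parameter name; map rows scoped to an experiment override the
shared binding, which is how two enzyme batches get distinct effective
$k_\mathrm{cat}$ values while sharing their $K_M$s.

Default priors: log-normal$(\log 10, 1)$ on turnover numbers (min$^{-1}$),
log-normal$(\log 100, 1)$ on Michaelis constants (µM), uniform$(1, 10^4)$
µM on inhibition constants, uniform$(1, 5)$ on Hill exponents, and
half-normal on each $\sigma_e$ with scale set to that experiment's observed
standard deviation (the noise scale must adapt to detector units; the data
enter only through an overall scale). All positive parameters are sampled
on the log scale and uniform-prior parameters through a scaled logit, with
transform Jacobians folded into the target density.

## Sampling

The posterior is explored with a No-U-Turn sampler (slice variant,
tree-doubling, dual-averaging step-size adaptation to a 0.9 target
acceptance, diagonal mass-matrix estimation in expanding warmup windows).
The likelihood gradient flows through the steady states via the
implicit-function-theorem sensitivities, and an analytic-vs-finite-difference
gradient check runs at initialization. Chains start from a jittered
posterior mode located by BFGS, with the initial diagonal metric taken from
the curvature at the mode; warmup adaptation then refines both. This
matters in practice: the mechanism posteriors have a ridge connecting the
inhibition regime ($K_I$ near its true value) to a no-inhibition plateau
($K_I$ large, rescaled $k_\mathrm{cat}$), and prior-median starts at short
warmup can strand chains on the plateau.

Diagnostics are split rank-normalized $\widehat{R}$ and bulk effective
sample size; more than 10% divergent transitions triggers a hard warning.
Fixed seeds give bit-identical draws.

## Model comparison

Hypotheses are ranked by PSIS-LOO. Importance ratios $1/p(y_i \mid
\phi_s)$ are Pareto-smoothed: the largest $\min(0.2S, 3\sqrt{S})$ ratios
are replaced by expected order statistics of a generalized Pareto
distribution fitted by the profile-likelihood posterior-mean shape
estimator (with a weakly informative shape prior), truncated at the raw
maximum. Points with tail shape $\hat{k} > 0.7$ are recomputed exactly: the
model is refitted on the data minus that observation (halved warmup) and
the held-out predictive density evaluated directly. The comparison table
reports each model's elpd with its standard error and the paired-difference
standard error against the top model; differences within roughly 2 SE are
not distinguishable.

## Synthetic campaigns

The generators produce observation tables with known ground truth by
solving the steady states under the true parameters and adding Gaussian
noise; negative draws are resampled rather than truncated so the Gaussian
observation model stays well-specified. True parameter values are
order-of-magnitude plausible for the enzymes emulated ($k_\mathrm{cat}$
20–45 min$^{-1}$, $K_M$ 100–400 µM, $K_I$ 100–1000 µM, $\sigma$ 3–15 µM);
corrupted experiments inflate $\sigma$ tenfold.

* `scenario_trypsin()`: two experiments on the uncompetitive-inhibition
  topology — inhibitor-free (`inflow_I = 0`) and inhibitor-present — over a
  six-point substrate grid in triplicate. The inhibitor-free experiment
  carries no information on $K_I$ (its posterior reproduces the prior); the
  inhibitor-present experiment couples $k_\mathrm{cat}$ and $K_I$ along a
  ridge; combining both collapses the ridge.
* `scenario_gdh_hk()`: sixteen experiments across three topologies
  (GDH-only, HK-only, combined GDH+HK with NADH-only observability), two
  GDH bead batches with distinct effective turnover numbers sharing their
  Michaelis constants, varying flow constants, inflows and bead loadings,
  and one HK experiment with 10× noise emulating an experiment containing
  an unknown error. Nested subsets of 4, 6 and 16 experiments support
  data-growth studies.
* `scenario_g6pdh(hypothesis)`: two experiments over a G6P × NAD inflow
  grid in triplicate, generated under any of H0–H4. The two reactors are
  deliberately contrasted: a long-residence-time, fully loaded reactor in
  which the product accumulates well past $K_I$ (probing the inhibition),
  and a short-residence-time, lightly loaded reactor staying below $K_I$
  (pinning the uninhibited kinetics). Without this contrast the
  inhibition is nearly unidentifiable from steady states alone — an
  informative fact about experimental design in such reactors.

What the generators do **not** emulate: detector physics (absorbance
spectra, chromatography), slow drifts or autocorrelated noise, bead-to-bead
heterogeneity, partitioning of substrate between bead interior and bulk,
and reversibility of the reactions. Passing recovery tests therefore show
the inference machinery is sound under its own assumptions, not that those
assumptions hold for any particular wet experiment.

## Study sizes and numerical choices

The validation studies run at reduced sizes chosen to keep the full suite
fast while leaving each check comfortably powered: the trypsin reference
fit uses 4 chains × 1000 draws (500 warmup) and is held to
$\widehat{R} < 1.01$; the single-experiment trypsin fits use 2 × 800
draws; the GDH/HK panel fits use 3 × 350 draws (4- and 6-experiment
subsets, where posterior-sd comparisons need small Monte-Carlo error) and
2 × 500 draws (full panel), with an $\widehat{R} < 1.05$ bar at these
sizes; the mechanism-recovery study uses 20 replicate datasets × 5
hypothesis fits at 2 chains × 150 draws (acceptance target 0.8, tree depth
capped at 5 — a capped trajectory is still valid NUTS, just shorter);
parameter recovery uses 30 reduced-size fits with a 95% ± 10 point
coverage band. Steady-state agreement checks run over 1000 random
condition draws against the closed form and against stiff integration run
to relative stationarity below $10^{-10}$. In posterior-sd comparisons
across growing datasets, an sd increase within twice its Monte-Carlo
standard error ($\mathrm{SE} \approx \mathrm{sd}/\sqrt{2\,\mathrm{ESS}}$)
is treated as a tie.

Other numerical choices: Newton tolerance $10^{-12}$ absolute and relative
(extent scale); central finite differences with relative step $10^{-6}$
wherever a derivative is verified; HDI mass 0.94 in `tidy()` summaries;
posterior-predictive intervals are empirical 2.5/97.5% quantiles; the
outlier rule flags experiments whose posterior-median $\sigma_e$ exceeds 3×
the cross-experiment median.

## Known limitations

Steady-state data cannot identify parameters that only shape transients;
strongly correlated ridges (e.g. $k_\mathrm{cat}$–$K_I$ under weak
inhibition) are faithfully reported as wide, correlated posteriors rather
than resolved; the diagonal mass matrix does not rotate away such
correlations, so effective sample sizes per draw are lower there; PSIS-LOO
comparisons lose robustness with few observations or many models, and a
hypothesis set that omits the true mechanism will still rank its members.
The CSTR model assumes ideal mixing and a strictly constant flow constant.
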