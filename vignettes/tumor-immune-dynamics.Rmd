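---
title: "Modelling colon tumor–immune dynamics from deconvolved cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling colon tumor–immune dynamics from deconvolved cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmekin)
```

## The model

`tmekin` implements a deterministic network model of the colon-cancer
immune microenvironment with fourteen state variables: nine cell
densities — naive (`TN`), helper (`Th`), cytotoxic (`TC`) and regulatory
(`Tr`) T cells, naive (`DN`) and activated (`D`) dendritic cells,
activated macrophages (`M`), cancer cells (`C`) and necrotic cells (`N`)
— and five cytokine pools: HMGB1 (`H`, the damage signal released by
necrotic cells), a carcinogenic pool `mu1` (IL-6/17/21/22), an
immunosuppressive pool `mu2` (IL-10/CCL20), interferon gamma and
TGF-beta. Cells are in cells/cm^3; cytokines are bulk RNA-seq expression
levels in arbitrary but cohort-fixed units. Time is in days.

The interaction structure is mass-action with a handful of standard
closures:

* Cytokines are produced linearly by their source cells and decay
  first-order. Fast interleukins (IL-2/4/5/12/13/23, TNF-alpha) are in
  quasi-equilibrium with their producing cells and are absorbed into the
  activation coefficients rather than tracked as states.
* T-cell activation terms multiply the naive pool `TN`, which caps the
  adaptive response and rules out unbounded exponential growth; `mu2` and
  `Tr` suppress helper and cytotoxic cells, `mu1` suppresses the
  regulatory lineage.
* Dendritic cells are activated by HMGB1 and by cancer-derived signals;
  HMGB1 also impairs their maturation, and cancer promotes their death.
  The activation and loss rates are shared between the naive and
  activated equations.
* Naive macrophages are not a state: the total capacity `M0 = MN + M` is
  conserved when the naive pool starts at its equilibrium, so recruitment
  draws on the reservoir `M0 - M` and `MN` is reported as `M0 - M`.
* Cancer follows logistic growth with capacity `C0`, the rate boosted by
  `mu1`, and per-capita losses to TGF-beta, interferon gamma, cytotoxic
  killing, and intrinsic death. A fraction `alpha_NC` of the death flux
  feeds the necrotic pool, which sources HMGB1 — the feedback loop that
  couples tumor death back into innate immunity.

With nonnegative rates and initial conditions the solution stays
nonnegative and bounded (`C` by `max(C(0), C0)`, `M` by `M0`); the test
suite checks these properties empirically on a 5000-day horizon for all
five shipped parameter sets.

## Parameters from steady states

No time-course data exist for untreated human tumors, so rate constants
are identified from a cross-sectional cohort: patients are clustered by
immune pattern, the large tumors of a cluster are assumed to sit near the
cluster's steady state, and the zeroed right-hand sides at that steady
state become the estimating equations. One scalar balance per equation
cannot pin down several rates, so a versioned YAML config
(`inst/extdata/assumptions.yaml`) closes the system with

* a fixed first-order decay rate (cytokines, macrophages, naive T cells),
  or a fixed per-capita turnover (T cells, dendritic cells, cancer), and
* nonnegative shares, summing to one per flux group, that apportion the
  balanced flux among an equation's production and loss terms.

Given those, `derive_parameters()` returns every rate in closed form and
the steady state is an equilibrium of the returned set by construction
(scaled residual at round-off). The cancer capacity is tied to the data
as `C0 = 2 C_inf`, so the logistic factor at the steady state is exactly
one half, and the necrotic decay rate closes the necrotic balance given
`alpha_NC` (default 0.5, i.e. half of dying cancer cells transit through
the necrotic stage).

The shipped defaults are deliberate placeholders pending
literature-derived values: shares are uniform within each flux group and
fixed rates are 1/day for the fast species (cytokines relax within days;
immune cell pools turn over on the order of a day in inflamed tissue).
The cancer equation is the exception, and the one genuinely open design
choice we resolved differently: its per-capita turnover defaults to
0.05/day with loss shares 0.3/0.05/0.15/0.5 on TGF-beta, interferon
gamma, cytotoxic killing and intrinsic death. Two observations force the
slow-cancer regime. First, tumors grow over months to years, not days;
with cancer turnover at 1/day the simulated tumors equilibrate within
about 45 days, collapsing the separation between cytokine relaxation and
tumor growth that motivates a stiff integrator in the first place (with
0.05/day the round trips converge in roughly 500 days). Second, the
printed small-tumor initial conditions have strongly elevated relative
interferon-gamma and cytotoxic levels in some clusters; if immune killing
carries a uniform quarter of the cancer loss, early death exceeds early
growth and the smallest tumors would shrink before growing, contradicting
the monotone growth this model family exhibits. Keeping immune-mediated
killing a modest fraction of cancer-cell loss is also what intravital
estimates of killing rates in established tumors suggest. These defaults
were fixed once, before the test expectations were frozen, and all
qualitative conclusions that depend on them are tested as soft
properties (warnings, not failures).

If a future transcription of literature values renders some cluster's
equilibrium unstable, the documented recourse is a coarse deterministic
grid over the share simplex (step 0.1) until the leading eigenvalue is
negative; with the shipped defaults all five printed equilibria are
attracting (leading eigenvalues about -0.05/day), so the search is never
entered.

`implied_assumptions()` inverts the construction — it reads off the
turnover rates and realized flux shares of any parameter set at its
equilibrium — which gives the identifiability loop used in the tests:
derive, invert, re-derive, and recover the original rates to 1e-8.

## Dynamics and non-dimensionalization

`simulate()` integrates with `deSolve`'s `lsoda`/`lsodar` (switching to
BDF under stiffness) using the hand-derived analytic Jacobian, relative
tolerance 1e-8 and absolute tolerance 1e-10 times a per-variable scale;
a root function stops the run once the scaled steady-state residual
drops below 1e-8. The default horizon is 10000 days with early exit.
Halving the tolerances moves the final state by far less than 0.1%.

Dividing each variable by a positive reference (its steady state) makes
the equilibrium the all-ones vector. `nondimensionalize()` represents
the rescaled system by exact conjugation — `F_bar(x) = F(x * ref) / ref`
— so no term is rewritten and the dimensional and dimensionless
trajectories are related exactly by the reference scales;
`dimensionless_coefficients()` exposes the per-term scaled rates for
inspection. References must be positive: a component that is numerically
zero (a cell type essentially absent from a cluster) is floored at 1e-6
times the cohort median of that variable by `floor_references()`, while
small-but-printed values pass through untouched.

`variation_envelope()` produces the one-at-a-time sensitivity bands:
each listed parameter is scaled by 0.9 and 1.1 (two runs per parameter,
never joint corners, keeping the run count linear) and the band is the
pointwise min/max across all runs plus the nominal.

## Sensitivity analysis

Three quantities of interest: cancer cell density, total cell density
(the nine cell variables; cytokines excluded, matching how "total cells"
is plotted in this model family), and the convergence eigenvalue of the
equilibrium Jacobian. Steady-state sensitivities come from implicit
differentiation — `J dX*/dtheta = -dF/dtheta` with both matrices
analytic — and the eigenvalue sensitivity from a central finite
difference (relative step 1e-4, halving it changes results by under 1%),
with the equilibrium re-solved by damped Newton at every perturbed
parameter vector and an eigenvalue-tracking check that warns if the
extremal eigenvalue changes identity across the stencil.

Reported sensitivities are elasticities on the dimensionless system:
state quantities are normalized by their steady-state reference and
derivatives are taken with respect to relative parameter changes. That
convention makes rankings invariant to the cohort's density scaling
(tested by rescaling a whole steady state and comparing), and it is the
right scale on which to compare a parameter with units of 1/day against
one with units of cm^3/cell/day.

"Convergence eigenvalue" is ambiguous in this model family: the slowest
mode (largest real part) governs the asymptotic approach, while the
literal minimum of the real parts is the fastest-decaying mode. We
report the literal minimum by default with a switch for the slowest mode
(`which = "max"`), and `stability_report()` returns both.

Because derived rates inherit uncertainty from the assumption shares,
pointwise sensitivities are also averaged over the hyperrectangle
`theta (1 +/- 0.1)` — the same 10% used for the trajectory bands, since
nothing in the estimation fixes a tighter neighborhood. The default rule
is a level-2 Smolyak sparse grid built from nested Clenshaw–Curtis
points (the center plus one pair of extremes per dimension, `2p + 1`
equilibrium re-solves for `p` parameters, exact through third order per
dimension with no cross terms — adequate because the elasticities are
nearly linear over a 10% box); a seeded Monte-Carlo average is available
as a fallback and agrees with the sparse rule within 5% of the largest
elasticity on the shipped parameter sets.

Under the shipped placeholder assumptions the top-ranked parameters for
cancer density are the cancer equation's own capacity and proliferation
and death rates in every cluster, and faster proliferation speeds
convergence while faster death slows it. The finer qualitative
structure — which immune parameter ranks first, and the sign pattern of
macrophage effects across clusters — depends on the literature values
behind the shares and is therefore asserted only softly.

## The cohort stage

`map_cohort()` turns a deconvolution fraction table plus tumor
dimensions into model variables. Tumor size is the product of the
longest and shortest dimension (cm^2); total cell density is
proportional to size, scaled so the cohort-mean tumor has
`alpha_dim = 1.125e5` cells/cm^3; each pooled immune variable is its
fraction scaled so the immune compartment totals `0.4 alpha_dim`; cancer
fills two thirds of the non-immune remainder, necrotic cells half the
cancer density. These conventions close `C + N + Immune = Total`
exactly, and the whole dimensionless pipeline is invariant to
`alpha_dim` (doubling it doubles every density and changes no
dimensionless output). As printed, the immune scaling fixes every
patient's total immune density at `0.4 alpha_dim`; an alternative that
scales immune density with tumor size would be a one-line change in
`map_to_model_variables()`, and we keep the fixed-total convention as
the reference behavior. Cytokine columns, when present, pass through
unscaled — they are expression levels, not densities.

The deconvolution-type-to-variable pooling
(`inst/extdata/celltype_mapping.yaml`) is data, not code: naive CD4 and
resting-memory CD4 pools feed `TN`, activated-memory CD4 and follicular
helper cells feed `Th`, CD8 plus activated NK feed `TC`, Tregs `Tr`,
resting/activated dendritic cells `DN`/`D`, M1 plus M2 macrophages `M`,
and the M0 fraction tops up the conserved capacity `M0`. Unmapped types
(B cells, monocytes, mast cells, ...) still count toward the immune
total and toward clustering.

Clustering runs K-means on all panel fractions (not the pooled
variables). The elbow rule deserves a note: the textbook
maximum-curvature criterion fails on realistic cohorts because the first
split of unevenly separated clusters produces the largest second
difference regardless of the true count. `elbow_k()` instead finds the
largest K whose inertia drop both dominates the plateau (5x the
tail-median drop) and is sharp (3x the next drop); a curve with no such
K — a single diffuse cloud — is flagged `confident = FALSE`. Per-cluster
steady states are the means over tumors larger than their cluster
average; initial conditions come from the cluster's smallest tumor, ties
broken by patient id.

## What the generator emulates — and what it does not

`generate_cohort()` draws, per patient: a planted cluster label; immune
fractions from a Dirichlet distribution centered on the cluster profile
(concentration 200, roughly matching the within-cluster spread of
deconvolved cohorts); a tumor size from a log-normal (median 0.6 cm^2,
sigma 0.5, spanning the sub-0.25 to above-1.25 cm^2 range of real
staging tables) truncated below half the median so every tumor has
measurable dimensions and a nonnegative mapped cancer density; an aspect
ratio for the two dimensions; cytokine levels log-normal around planted
cluster means (CV 0.15); and synthetic clinical labels. Default planted
profiles are proportional to the shipped per-cluster steady-state
densities, scaled by one common factor (~0.91) so every cluster fits on
the fraction simplex under the fixed-immune-total mapping — the printed
immune blocks of three clusters sum slightly above `0.4 alpha_dim` and
are therefore not exactly reachable as mapped outputs; the common factor
preserves every between-cluster contrast. Because cancer density is a
deterministic function of size, the cancer-to-immune ratio rises with
tumor size by construction, reproducing the size-stratified trend such
cohorts show.

Not emulated: gene-expression noise upstream of deconvolution (fractions
are drawn directly), correlations between immune pattern and tumor size,
censored survival structure in the clinical labels, and any real
biological coupling between cytokine levels and cell fractions. Passing
the pipeline tests on this generator therefore demonstrates the
machinery — mapping, clustering, extraction, estimation, simulation —
not the biological fidelity of deconvolution itself.

One statistical caveat is baked into the tests: a planted fraction of
order 1e-6 (the near-zero naive-dendritic pool of one cluster) gives a
Dirichlet component whose finite-sample mean is essentially zero with
rare spikes; central-limit checks are meaningless there, so recovery
tests cover only components with planted concentration at least 0.1 and
allow the occasional marginal exceedance a hundred simultaneous 3-SE
comparisons must produce.

## Numerical choices, degenerate inputs, limitations

* Newton re-solves of the equilibrium use the analytic Jacobian with
  backtracking line search, tolerance 1e-12 on the scaled residual.
* The steady-state residual is always reported relative to a
  per-variable scale; for a floored near-zero reference the flux balance
  cancels catastrophically relative to that scale, which bounds the
  achievable residual near `flux * eps / floor` — the synthetic-pipeline
  tests use 1e-8 there while the printed tables meet 1e-10.
* Ties in size are broken by patient id; zero fractions are kept until
  non-dimensionalization, which applies the documented floor.
* Problem sizes in the shipped tests: 300-patient cohorts, K = 5,
  5000–10000-day horizons, 1000-node Monte-Carlo cross-checks; the whole
  suite runs in well under a minute.
* The model is spatially homogeneous and deterministic: no PDE
  extension, no stochastic dynamics, no treatment terms. Parameter
  identification rests on the cross-sectional steady-state assumption —
  large tumors of a cluster are treated as the future of its small
  tumors — which time-course data would be needed to validate.
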