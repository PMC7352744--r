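---
title: "Mixture design, Scheffé modelling and aerosol metrics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture design, Scheffé modelling and aerosol metrics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixaero)
```

# The model and its assumptions

A mixture experiment varies the proportions of q components that sum to a
fixed total. The feasible region here is the intersection of the simplex
with per-component bounds, $L_j \le x_j \le U_j$, $\sum x_j = 100$ wt%.
For the nanoemulsion system shipped as the reference dataset the
components are an oil mixture (A), lecithin (B), a surfactant mixture
(C), glycerol (D) and water (E), with bounds (4–6, 2–3, 1–2, 1.5–3,
86–91.5) wt%; the water bounds are exactly those implied by the others,
so water acts as the filler.

Responses are modelled by Scheffé canonical polynomials, which have no
intercept because the mixture constraint makes a constant column
redundant. The quadratic model in five components has 15 terms (5 singles
plus 10 pairwise products), the special cubic 25. Fitting assumes
independent homoscedastic Gaussian errors — the implicit assumption of
the ordinary-least-squares/ANOVA pipeline — and the synthetic-data
generator reproduces exactly that structure.

## Pseudo-component coding

All fitting, design selection and coefficient reporting use
L-pseudo-components,
$x'_i = (x_i - L_i) / (100 - \sum_j L_j)$,
which map the bounded region onto the unit simplex. Two reasons:

* conditioning — in raw proportions the region is a thin sliver near the
  water vertex and the quadratic model matrix is nearly collinear;
* comparability — the published regression equations for this system
  only reproduce their own printed predictions when evaluated in this
  coding (e.g. the quadratic particle-size equation gives 97.15 ≈ the
  printed 97.2 nm at the optimized composition), so the package reports
  coefficients on the same scale.

Because the quadratic Scheffé space is closed under affine re-coding of
the simplex, fitted values are identical whichever coding is used (a
property the test suite asserts); only the coefficient values change.
Refitting with a zero-lower-bound region provides real-proportion
coefficients when needed.

# Design construction

Candidate points are the classic extreme-vertex set: every vertex of the
constrained region (at least $q-1$ bounds active), the centroid of every
face (computed as the mean of the vertices sharing a set of active
bounds, which yields edge midpoints and higher-order face centroids),
and the overall centroid. For the reference region this reduces to the
3-level grid $\{L, (L+U)/2, U\}$ over the four free components — 81
candidates containing all 20 distinct compositions of the published
24-run design.

D-optimal selection maximizes $\det(X'X)$ of the pseudo-coded model
matrix by greedy point exchange with seeded random restarts (default
10), accepting at each step the best single swap between a design point
and a candidate; ties break toward the first candidate index, and the
determinant is recomputed from scratch at each accepted swap because the
designs involved are tiny (tens of runs, ≤ 25 terms). The objective is
non-decreasing by construction and on small instances the search matches
exhaustive enumeration (asserted within 1% in the tests). Replicate
slots append copies of the overall centroid — mirroring the reference
design's four centroid runs — or optionally of the selected point with
maximum leverage. Exact reproduction of the published 24 rows is not a
goal: the published candidate list and exchange internals are not
available, so the contract is D-efficiency parity, and the selected
design's $\det(X'X/n)^{1/p}$ exceeds the published design's by ~6%.

# Diagnostics

The ANOVA decomposes the mean-corrected total SS. Mean correction is
legitimate despite the no-intercept parameterization because the model
columns sum to one under the mixture constraint, so the response mean is
a nested null model; it is also the convention under which the reported
R² magnitudes (0.9922 for the DTX particle size) are reproducible —
uncorrected totals give values indistinguishable from 1.

* Model df is $p - 1$ (the constraint absorbs one), residual df $n - p$.
* Interaction terms are tested by partial (single-term-deletion) SS;
  single-component terms receive no individual test because they are not
  separately estimable effects in the Scheffé parameterization. No
  multiplicity correction is applied across the term tests.
* Pure error pools within-replicate-group squared deviations. Replicates
  are detected automatically (compositions equal to 1e-9); in the
  reference design this finds both the centroid quadruple and a
  duplicated vertex pair, giving pure-error df 4 — the split under which
  the published lack-of-fit F of 2.28 is reproduced (we compute 2.30).
* Adequate precision is the fitted-value range over the average
  prediction standard error $\sqrt{p\,MS_{res}/n}$; values above 4
  indicate usable discrimination.
* Model-order selection fits every estimable order and keeps the highest
  one whose *added* terms are jointly significant by a sequential F-test
  (the overall model F for the linear model), whose lack of fit is
  insignificant, and whose adjusted R² improves on the incumbent. The
  sequential test (rather than the overall model F at every order) is
  what protects a linear truth from being over-modelled: with the
  overall-F rule a quadratic refit of linear-truth data is almost always
  "significant" because the linear terms carry it, and simulation shows
  linear would then be chosen only ~60% of the time, versus >90% under
  the sequential rule.

Recomputing the published statistics from the printed 24-run table
reproduces most of them within a fraction of a percent (see
`analysis/02_fit_models.R` and `scripts/acceptance.R`). Two quantities
land a few percent off no matter the convention — the DTX particle-size
model F (84.4 recomputed vs 81.3 reported) and the CCM particle-size
adequate precision (68.0 vs 64.9) — with the discrepancy traceable to
the residual mean square (0.449 recomputed vs 0.47 reported while the
model MS agrees exactly), i.e. to the printed responses differing
slightly from the values originally fitted. One printed value is
irreconcilable: the CCM VMD linear fit gives R² = 0.048 from the printed
responses against a reported 0.7610; the package reports the honest
recomputation.

# Optimization and validation

Multi-response optimization uses Derringer-style desirabilities:
per-goal scores in [0, 1] (one-sided ramps for minimize/maximize, a
triangular ramp for target, an indicator for in-range) combined as a
weighted geometric mean, so any fully failed goal zeroes the product.
The optimizer lays a 21-level lattice over the free components (water by
difference, infeasible points dropped), then refines the best point by
halving a 5-level local lattice until the step is below 1e-7 wt% —
deterministic, and never worse than the best lattice point. The kinked
(non-smooth) maxima of target goals are found reliably by this
derivative-free scheme.

The shipped goal configuration (`dcn_goal()`,
`inst/extdata/dcn_goal.yaml`) reproduces the study's reported optimum of
6.0/2.5/2.0/2.5/87.0 wt%. This configuration is necessarily not pure
response minimization: under the published equations the reported
optimum is dominated — more than a thousand feasible compositions
predict smaller particle size *and* smaller VMD for both drugs — so a
goal that recovers it must encode composition preferences. The shipped
file minimizes all four responses over windows spanning their
design-space prediction ranges and adds component directives at weight
3: oil maximized (payload capacity of the lipophilic drugs), surfactant
maximized (both sizes fall with surfactant), lecithin and glycerol
targeted at 2.5 wt%. Other defensible configurations (e.g. equal-weight
response minimization) yield different optima — typically low-oil,
high-surfactant vertices — so reproduction of the reported composition
is a property of this fixture, not of desirability optimization per se.

Validation compares measured responses at external formulations with
model predictions via RSE(%) = 100(actual − predicted)/predicted,
flagging |RSE| above 5% by default. Against the published equations the
eight reference formulations stay within 2.2% for particle size and
3.8% for VMD, matching the reported bounds.

# Aerosol metrics

From laser-diffraction percentiles: span = (DV90 − DV10)/DV50. From
cascade-impactor stage depositions (stages labelled 0–7 plus filter,
strictly decreasing lower cutoff diameters):

* ED = all mass on device parts + stages; PD = 100·ED/TD;
  PI = 100·(stage mass)/TD. Whether "stages 0 to 7" includes the back-up
  filter is ambiguous in common usage; the package includes it by
  default (`pi_include_filter = FALSE` gives the strict reading). Either
  way PI ≤ PD.
* MMAD is the 50th percentile of the cumulative mass-undersize curve
  built at the stage cutoffs, interpolated linearly in log₁₀(diameter);
  GSD = √(d(84.13%)/d(15.87%)) by the same interpolation. Log-linear
  interpolation is standard impactor practice and consistent with the
  lognormal definition of GSD; probit-scale interpolation — exact for a
  lognormal — is available via `interpolation = "probit"`. Zero-mass
  stages create plateaus in the curve; interpolation trims each plateau
  to its innermost cutoffs so a jump is bracketed by its actual
  collection window. Percentiles outside the curve extrapolate from the
  end segment with a warning.
* FPF = 100·(stage 4 through filter)/ED, with the starting stage
  configurable.

The default cutoff table carries the four stage windows documented for
this system (3.3–4.7, 2.1–3.3, 1.1–2.1, 0.65–1.1 µm for stages 3–6)
plus nominal values for the remaining stages; a calibrated table for the
operating flow rate should replace it where available, since cutoffs
shift with flow.

# Synthetic data: what it does and does not emulate

`simulate_responses()` adds i.i.d. Gaussian noise to a known Scheffé
surface — matching the homoscedasticity assumption of the analysis, and
deliberately *not* simulating run-order drift, blocks, or
composition-dependent variance that real formulation campaigns can
exhibit. Passing recovery tests therefore demonstrates correctness of
the estimation pipeline under its own assumptions, not robustness to
their violation. At the residual scale of the reference fit
(sd ≈ 0.7 nm), refit R² values bracket the reported 0.9922, anchoring
the simulation to the observed noise level.

`simulate_impactor()` draws mass quanta from a lognormal aerodynamic
distribution and bins them by cutoff window, with a fraction of the dose
retained in the nebulizer and a small fraction of the emitted dose on
the inlet assembly. It ignores evaporation during transit (the mechanism
suspected of inflating laser-diffraction sizes relative to impactor
sizes), inter-stage wall losses, and re-entrainment. Recovery of the
generating parameters (MMAD 3.2 ± 0.15 µm, GSD 1.7 ± 0.1 at 10⁶ quanta)
verifies the summary pipeline including the discretization and
interpolation bias of the log-linear rule, which is visible as a GSD
estimate of ≈ 1.77 against a generating 1.7 (the probit rule recovers
1.70).

# Numerical choices and problem sizes

* Least squares by QR (`lm.fit`); the normal-equation solve is kept as
  an independent oracle in the tests (agreement to 1e-8).
* Composition equality and simplex-sum tolerances are 1e-9; bound checks
  allow 1e-8 slack for rounded inputs.
* An interpolating fit (residual MS numerically zero) reports infinite
  adequate precision with a warning rather than overflowing.
* Degenerate regions (Σ lower = total) are rejected at pseudo-coding
  time; bound-collapsed free components are rejected by the surface
  grid.
* Test problem sizes: exchange-vs-exhaustive checks enumerate ≤ 7-point
  candidate sets; null-calibration of the model F uses 500 seeded
  pure-noise simulations (rejection at α = 0.05 lands within 5% ± 2.5%);
  impactor recovery uses 10⁵ quanta in the unit tests and 10⁶ in the
  acceptance suite. These sizes were chosen so that the whole suite runs
  in about a minute while keeping Monte-Carlo error well inside the
  asserted tolerances.

# Known limitations

* No blocking, split-plot, or multiple-total (amount) designs; no full
  cubic or quartic Scheffé models; no Cox-direction effect displays.
* No PRESS/predicted-R², Box–Cox transforms, or outlier diagnostics.
* The desirability optimizer targets a single global optimum by grid
  seeding; it does not enumerate Pareto fronts and can in principle miss
  a global optimum narrower than the seeding lattice spacing.
* Impactor metrics treat stage cutoffs as sharp; real collection
  efficiency curves are sigmoidal.
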