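# mixaero

Mixture design of experiments, Scheffé polynomial modelling, and aerosol
performance metrics for drug-loaded nanoemulsion formulation.

## The problem

Inhalable nanoemulsions carry hydrophobic drugs (here docetaxel, DTX, and
curcumin, CCM) to the deep lung. Their two critical quality attributes —
emulsion particle size (nm) and nebulized aerosol size (volume median
diameter, VMD, µm) — are driven by the formulation composition: oil,
lecithin, surfactant mixture, glycerol, and water, in wt% summing to 100.
Because the factors are proportions of a whole, ordinary factorial designs
do not apply; the design space is a bounded slice of a simplex
(L<sub>j</sub> ≤ x<sub>j</sub> ≤ U<sub>j</sub>, Σx<sub>j</sub> = 100) and
the models are Scheffé canonical polynomials with no intercept:

- linear: ŷ = Σ β<sub>i</sub> x′<sub>i</sub>
- quadratic: ŷ = Σ β<sub>i</sub> x′<sub>i</sub> + Σ<sub>i&lt;j</sub> β<sub>ij</sub> x′<sub>i</sub> x′<sub>j</sub>
- special cubic: adds Σ β<sub>ijk</sub> x′<sub>i</sub> x′<sub>j</sub> x′<sub>k</sub>

where x′ are L-pseudo-components, x′<sub>i</sub> = (x<sub>i</sub> −
L<sub>i</sub>)/(100 − ΣL). The package implements the full computational
pipeline around these models, for formulation scientists running
design-of-experiments optimization of aerosol drug products:

1. **Design** — candidate points (extreme vertices, face centroids,
   overall centroid) on the constrained simplex and D-optimal run
   selection by point exchange, maximizing det(X′X).
2. **Fit & diagnose** — no-intercept least squares, mixture ANOVA with
   partial (single-term-deletion) F-tests, lack-of-fit versus pure error
   from replicates, R², adjusted R², adequate precision, and model-order
   selection by sequential F-tests.
3. **Optimize & validate** — Derringer desirability (weighted geometric
   mean) over response and component goals with grid seeding plus local
   refinement, and external validation by residual standard error,
   RSE(%) = 100·(actual − predicted)/predicted.
4. **Aerosol metrics** — span = (DV90 − DV10)/DV50 from laser-diffraction
   percentiles; emitted dose, percent dispersed/inhaled, MMAD (50th
   percentile of the cumulative mass-undersize curve, interpolated in
   log diameter), GSD = √(d84.13/d15.87), and fine particle fraction from
   cascade-impactor stage depositions.
5. **Synthetic data** — seeded generators for responses (Scheffé surface
   plus Gaussian noise) and impactor runs (lognormal aerodynamic
   distribution), so every stage is testable without laboratory data.

The reference dataset of a published DTX/CCM nanoemulsion study (24-run
D-optimal design, four responses, validation formulations, aerosol
summaries, and the four published regression equations) ships with the
package (`dcn_design()`, `dcn_models()`, `dcn_validation()`,
`dcn_aerosol()`, `dcn_region()`, `dcn_goal()`).

## Worked example

```r
library(mixaero)

d <- dcn_design()
fit <- fit_scheffe(d$design, d$responses$ps_dtx, "quadratic")
r_squared(fit)            # 0.992439
adequate_precision(fit)   # 36.33816

at <- mixture_anova(fit)
at$rows[at$rows$term %in% c("Model", "Lack of fit"), c("term","df","ms","f")]
#          term df        ms        f
#         Model 14 37.85580 84.380276
#   Lack of fit  5  0.59936  2.303238

predict(dcn_models()$ps_dtx, c(6.0, 2.5, 2.0, 2.5, 87.0))  # 97.1543 nm
rse_percent(95.8, 97.2)                                    # -1.440329
span(2.50, 5.48, 11.48)                                    # 1.638686
```

The quadratic fit explains 99.2% of the particle-size variation with a
signal-to-noise (adequate precision) far above the usable threshold of 4;
the lack-of-fit F of 2.30 against pure error is insignificant, so the
quadratic surface is adequate. The published DTX equation predicts
97.2 nm at the optimized composition, within 1.44% (RSE) of the measured
95.8 nm, and the reported laser-diffraction percentiles give a span of
1.64.

The full analysis is scripted under `analysis/`
(`01_design.R` … `04_aerosol.R`); each step prints its findings and
writes tables under `results/`.

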