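---
title: "Hindcasting vegetation belts with presence-background niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hindcasting vegetation belts with presence-background niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoveg)
```

## The problem

Tropical mountain vegetation is organized in altitudinal belts — an
afroalpine belt (AA) on the summits, an ericaceous shrub belt (EB) beneath
it, dry and moist Afromontane forests (DAF, MAF) at mid elevations,
Acacia–Commiphora and Combretum–Terminalia woodlands (ACB, CTW) in the warm
lowlands, and desert scrub (DSS) on the hottest, driest floor. Where each
belt sat during the late Glacial and the Holocene is a question that fossil
pollen alone answers only locally. `paleoveg` reconstructs belt positions
regionally: it fits a climatic niche model per vegetation unit from
present-day occurrences, projects the fitted models onto past climate
grids, corrects for the physiological effect of low glacial CO₂, and
composites the per-unit suitabilities into one categorical vegetation map
per time slice, which can then be summarized (areas, elevation limits) and
confronted with pollen records.

Because the real input rasters are large external downloads, the package
ships a synthetic-landscape generator that reproduces the statistical
structure the method relies on. Everything below runs on synthetic data;
the same functions accept real grids read with `read_climate_stack()`.

## The niche model

Each vegetation unit is modeled from presences and background with a
maximum-entropy (Gibbs) model. Over a background sample of landscape cells
\(x\) with features \(f(x) \in [0,1]^m\), the model is
\[ q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z_\lambda}, \qquad
   Z_\lambda = \sum_{x'} e^{\lambda \cdot f(x')}, \]
and the weights maximize the penalized presence likelihood
\[ \frac{1}{n}\sum_{i=1}^{n} \lambda \cdot f(x_i) \;-\; \log Z_\lambda
   \;-\; \beta \sum_j s_j |\lambda_j|, \]
with \(s_j\) the presence standard error of feature \(j\)
(\(\mathrm{sd}/\sqrt{n}\), floored at \(10^{-3}\)) and \(\beta\) a global
regularization multiplier (default 1). At the optimum the KKT conditions
bound every feature's discrepancy:
\(|\bar f_j^{\text{presence}} - E_q[f_j]| \le \beta s_j\).

Two conventions matter and are deliberate:

* **Features.** Linear, quadratic, pairwise-product and hinge classes, the
  large-sample default of maximum-entropy SDM tools; hinges use 31 interior
  knots per variable in both directions. All features map the scaled
  \([0,1]\) predictors into \([0,1]\), so one \(\beta\) is comparable
  across classes.
* **Samples in the background.** The training presences are added to the
  background sum defining \(Z\). Without this, any feature whose presence
  mean exceeds its background maximum (easy to arrange with products and
  hinges) separates the classes and the penalized likelihood is unbounded —
  the fitted weights run away. With it, the objective is always bounded.

The solver is a two-phase convex optimizer written in C++: a monotone
accelerated proximal-gradient phase, then active-set coordinate descent
with a Levenberg-damped orthant Newton polish, run to a KKT residual of
\(10^{-6}\). The accepted objective sequence is non-increasing and is
stored on the model for inspection. Non-convergence raises a condition
carrying diagnostics rather than returning a half-fitted model.

Predictions come in two forms: `raw`, the relative occurrence rate
\(q_\lambda\) (sums to 1 over the training cells), and `cloglog`,
\(1 - \exp(-e^{H} q_\lambda(x))\) with \(H\) the entropy of the fitted
background distribution, a bounded \([0,1]\) probability-of-occurrence
scale. Compositing and the CO₂ correction operate on cloglog values;
AUC is rank-based and identical under either output.

```{r fit-small}
spec <- landscape_spec(n_rows = 60, n_cols = 60, seed = 7)
present <- generate_climate_stack(spec)
truth <- generate_true_vegetation(present, default_niches())
occ <- sample_presences(truth, "DAF", n = 500, seed = 1)
parts <- split_occurrences(occ, test_fraction = 0.25, seed = 2)
bg <- sample_background(present, 2000, predictors = default_predictors(),
                        seed = 3)
m <- fit_maxent(parts$train, bg, present, n_hinge_knots = 11)
evaluate_auc(m, parts$test, bg, present)$auc
```

## Predictor screening

Candidate predictors are the 19 bioclim summaries. Collinearity is screened
with pairwise Spearman rank correlation (average ranks for ties) and a
greedy elimination: repeatedly drop the non-protected variable with the
most partners above the threshold (ties broken toward the later name in the
input order, so the outcome is deterministic) until no resolvable pair
exceeds it. The threshold default is \(|\rho| = 0.85\); the literature this
reconstructs does not state a numeric cut, so the default keeps the nine
conventional predictors (`default_predictors()`) as explicit
keep-overrides — correlated pairs among them (e.g. mean annual temperature
and coldest-month minimum) are retained on the usual argument that they
carry complementary causal information. On the synthetic 19-layer stack the
screen reproduces exactly that nine-variable outcome; both the threshold
and the overrides are arguments, not constants.

## Hindcast projection and the CO₂ correction

Projection applies a fitted model to a past climate stack using the
training-time feature scaling. Predictor values outside the training range
are clamped to the boundary and flagged in a clamping mask (on by default);
projecting onto the training stack reproduces the training prediction
bit-for-bit, the standard control test.

Low glacial CO₂ suppresses tree growth and favors C4-dominated open
vegetation independently of climate. The package represents this as a
per-unit correction factor applied to the projected probability of
occurrence. Each unit carries a base factor \(f_{\mathrm{LGM}}\) — its
fraction cover under glacial CO₂ divided by its cover under modern CO₂, as
estimated by dynamical vegetation model experiments — anchored at a glacial
concentration \(c_{\mathrm{LGM}}\) (default 185 ppm) and a no-effect
reference \(c_{\mathrm{ref}}\) (default 280 ppm, pre-industrial). Assuming
the effect scales linearly with concentration,
\[ \mathrm{factor}(c) = 1 + (f_{\mathrm{LGM}} - 1)
   \frac{c_{\mathrm{ref}} - c}{c_{\mathrm{ref}} - c_{\mathrm{LGM}}}, \]
equal to \(f_{\mathrm{LGM}}\) at the glacial anchor, exactly 1 at and above
\(c_{\mathrm{ref}}\), extrapolated but floored at 0 below
\(c_{\mathrm{LGM}}\). Corrected probabilities are clipped to \([0,1]\); a
surface can be corrected once (a flag guards double application), and no
cross-unit renormalization is performed — the correction is a per-unit
statement about growth, not a reallocation of probability mass. The
shipped `default_correction_table()` is synthetic (forests 0.7–0.85,
open units 1.1–1.3): published per-unit factors live in supplementary
material outside this package's inputs, so real analyses should supply
their own table via `correction_table()`.

## Compositing and summaries

`composite_vegetation()` performs the cell-by-cell analysis: each cell
takes the unit with the highest corrected suitability, unless that maximum
falls below the no-analog threshold (default 0.1, the conventional "low
probability" cut), in which case the cell is left unassigned — climate
there suits none of the modeled units. Exact ties go to the first unit in
the configured order, which is recorded in the map provenance. Masking
happens after the argmax, so raising the threshold can only grow the
no-analog class. Areas are cell counts times the cell area (no geodesic
correction on synthetic grids); elevation limits are the 2nd/98th
percentiles of a unit's cell elevations — percentiles rather than extremes
so a single outlying cell cannot move a belt boundary.

```{r composite}
past <- generate_climate_stack(spec, age_ka = 22)
s22 <- project_model(m, past)
f22 <- correction_factor(default_correction_table(), "DAF",
                         co2_at(generate_co2_series(22:0), 22))
c22 <- apply_correction(s22, f22)
range(c22$values)
```

## The synthetic landscape

The generator emulates exactly the features the analysis depends on:

* **Terrain.** Smoothed Gaussian noise plus one deterministic ridge,
  rescaled to \([0, 4500]\) m and right-skewed so highlands are a small
  minority of the area, as on real massifs.
* **Temperature.** Every temperature layer is
  `sea_level_temp − lapse_rate × elevation/100` plus a layer-specific
  seasonal offset; the lapse-rate default 0.6 °C/100 m is the midpoint of
  the 0.5–0.7 range reported for tropical highlands. With
  `seasonal_contrast = 0` the offsets are spatially constant and a
  regression of any temperature layer on elevation recovers the lapse rate
  to machine precision; the default setting modulates seasonal range by
  local dryness, which is what gives the derived 19-layer set its
  realistic collinearity structure.
* **Precipitation.** A linear spatial gradient plus smoothed noise,
  floored at zero; past slices scale it multiplicatively.
* **Past anomalies.** Temperature offset linear in age (−6 °C at 22 ka)
  and precipitation scale 0.8 at 22 ka, i.e. cold dry glacial conditions
  relaxing linearly to the present.
* **CO₂.** A monotone piecewise-linear ramp 185 → 280 ppm between 22 ka
  and the present through deglacial anchor points.
* **Vegetation truth.** Product-Gaussian climatic envelopes per unit with
  argmax assignment and the same 0.1 no-analog rule; defaults place the
  seven units in the altitudinal belt order described above.
* **Pollen.** One sample per slice; unit-group proportions proportional to
  \(e^{-d_g/\delta}\) with \(d_g\) the distance to the nearest mapped cell
  of the group's unit (\(\delta\) = 20 km, a typical regional pollen
  transport scale), split evenly among the group's taxa, plus fixed
  wetland (12%) and ambiguous (8%) background; counts are multinomial.

Every generator is a pure function of its spec and seed. The default grid
is 200 × 200 cells at 1 km — a desk-scale analog of a 1-km national
raster. Unstated magnitudes (noise s.d.s, seasonality coefficients, the
anomaly endpoints, presence counts fixed at 1000 per unit within the
1000–10 000 convention) were chosen once as field-plausible values and are
documented in the signatures.

What passing on this landscape does *not* show: the generator has no
spatial autocorrelation in occurrences beyond the belt geometry, no
observation error in presences, no orographic rain shadows, no
non-stationary lapse rate, and climate perfectly determines the truth — so
model performance here is an upper bound, and the pipeline's correctness,
not its real-world skill, is what the tests establish.

## Numerical choices and degenerate inputs

* Solver: KKT tolerance \(10^{-6}\), iteration cap 200 000, convergence
  error (not a warning) on failure.
* Holdout size uses `floor(test_fraction × n)`.
* Histogram bins are equal-width spanning `[min, max]`; a constant sample
  widens its range by ±0.5 to stay well-defined.
* Constant raster layers yield undefined Spearman correlations, reported
  `NA` with a warning and never counted as above-threshold by the screen.
* Compositing ties break to the configured unit order; argmax is invariant
  to any common strictly monotone rescaling of all surfaces.
* Pollen samples whose assigned-taxa sum is zero are reported missing, not
  dropped silently; excluded taxa sit outside both numerator and
  denominator of the percentages (alternative pollen-sum conventions can be
  had by editing the grouping).
* Concordance (Spearman between a group's percentages and negative habitat
  distance across ages) needs ≥ 3 paired ages and is `NA` when either
  series is constant. The statistic itself is this package's
  operationalization of a comparison that is classically done visually;
  treat it as a summary, not an inference.

## Known limitations

* The categorical composite hides within-cell mixtures and transitional
  vegetation; cells near the argmax boundary flip under small suitability
  changes (the CO₂-correction area effects live exactly there).
* The linear CO₂-effect model is a first-order assumption anchored at two
  points; nothing in the data constrains its shape between them.
* Elevation limits on coarse grids are quantized by the hypsometry of the
  synthetic terrain.
* The screening's greedy elimination is deterministic but not guaranteed to
  find a maximum-size below-threshold subset in adversarial correlation
  structures (tests compare it against exhaustive search on small cases).
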