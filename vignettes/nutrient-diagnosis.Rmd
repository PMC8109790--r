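---
title: "Factor-specific cranberry nutrient diagnosis and carryover yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-specific cranberry nutrient diagnosis and carryover yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranberrydx)
```

## The problem

Cranberry (*Vaccinium macrocarpon*) fertilization is traditionally guided by
fixed "sufficiency ranges" for tissue nutrient concentrations, averaged
across regions, cultivars, soils and management. Such across-factor norms
assume that everything except the nutrient under scrutiny is near optimum —
an assumption that rarely holds on a given bed. This package implements a
factor-specific alternative: diagnose a bed against *successful neighbours*
— observed beds that produced high yield under comparable conditions — in
the geometry appropriate for concentration data, and predict what the bed
could yield, this year and next, if its nutrient profile were rebalanced.

## Tissue tests as compositions

A tissue test reports 10 nutrient concentrations (N, P, K, Mg, Ca, B, Cu,
Zn, Mn, Fe, in g/kg dry weight). Concentrations are *compositional*: they
live on a simplex, because the 10 nutrients plus the rest of the dry matter
must account for the 1000 g/kg measurement unit. The package closes every
tissue test with a filling value,

$$F_v = 1000 - \sum_{i=1}^{10} x_i,$$

giving an 11-part composition. All downstream operations use log-ratio
geometry:

* **clr** (centred log ratio): $\mathrm{clr}_i = \ln(x_i / g(\mathbf{x}))$,
  with $g$ the geometric mean over the 11 parts. clr vectors sum to zero.
* **ilr** (isometric log ratio) under a *sequential binary partition*:
  for a contrast opposing $r$ parts to $s$ parts,
  $\mathrm{ilr} = \sqrt{rs/(r+s)}\,\ln(G_r/G_s)$, with $G_r, G_s$ the
  geometric means of the two groups. The D−1 = 10 balances form an
  orthonormal basis, so distances in ilr coordinates equal distances
  between clr vectors for *any* valid partition.
* **Aitchison distance** $\varepsilon$: the Euclidean distance between two
  compositions in clr/ilr space. This is the yardstick for "nearest
  successful neighbour".
* **Perturbation vector** $p = X \ominus x^\ast$: the part-wise ratio of a
  diagnosed composition to a reference. Ratios above 1 read as relative
  excess, below 1 as relative shortage; ranking nutrients by
  $|\ln(\text{ratio})|$ orders them by their departure from balance.

Two conventions matter and are fixed deliberately:

* distances are computed over all 11 parts *including* the filling value —
  this convention reproduces the published worked diagnoses (0.66, 1.64,
  0.99) from their printed concentrations;
* the default partition first opposes the 10 nutrients to the filling
  value, then macronutrients (N, P, K, Mg, Ca) to micronutrients (B, Cu,
  Zn, Mn, Fe), then peels parts off left to right within each group. Below
  the macro/micro split the cascade order is a package convention;
  distances are invariant to it, only the coordinate values depend on it.

Zero or missing concentrations are rejected rather than imputed: log-ratio
operations are undefined at zero and no replacement rule would be neutral.

```{r worked}
defective <- close_composition(c(12.1, 1.1, 4.0, 1.5, 8.2,
                                 0.030, 0.005, 0.030, 0.220, 0.090))
successful <- close_composition(c(10.1, 1.0, 4.7, 1.9, 9.0,
                                  0.029, 0.006, 0.018, 0.222, 0.097))
round(aitchison_distance(defective, successful), 2)
rank_nutrients(perturbation(defective, successful))
```

## Classification about the yield cutoff and the reference bank

Who counts as a "successful neighbour"? A random-forest classifier is
trained to predict whether a bed exceeds the yield cutoff (default 40
ton/ha, well above the regional average of roughly 30) from the documented
features: region, cultivar, farming system, seasonal fertilization, the
tissue composition (as ilr coordinates), soil tests, grain-size fractions,
bulk density, soil series, and monthly climate. Performance is assessed by
stratified k-fold cross-validation (k ∈ {5, 10, 20}, default 10 as the
middle option) using classification accuracy (CA) and AUC, with the model
considered informative when AUC > 0.7.

Crossing the *observed* class with the *out-of-fold predicted* class splits
the specimens into confusion-matrix quadrants: true negatives
(high-yielding, predicted balanced), false negatives (low-yielding but
predicted balanced), false positives (high-yielding despite a predicted
imbalance) and true positives (low-yielding, predicted imbalanced). The
true negatives form the **reference bank** — the diagnostic standards.
Out-of-fold rather than refit-on-all predictions define the quadrants; the
refit alternative would admit optimistically misclassified specimens into
the bank. False positives are always excluded (their high yields come with
luxury consumption or contamination); false negatives can be appended
explicitly when true negatives are scarce. Forest hyperparameters are fixed
(500 trees, square-root feature sampling, seeded) rather than tuned:
stability of the bank matters more than squeezing out accuracy. Predicted
probabilities tying at exactly 0.5 resolve to "imbalanced", an arbitrary
but documented convention.

Diagnosis then takes two complementary forms:

* **local**: against the nearest bank specimen by Aitchison distance
  (ties broken by higher yield, then bank order), optionally restricted to
  the same cultivar and/or region; the neighbour's observed yield is the
  *attainable yield*;
* **regional**: against the arithmetic mean of the bank concentrations,
  re-closed (a geometric-mean variant is available; the averaging
  convention for published regional distances could not be established, so
  both are offered). No attainable yield is attached: an average is not an
  observed bed.

Quartile concentration ranges (linear-interpolation definition, R type 7)
over the bank summarize the compatibility intervals of balanced tissue.

## Carryover: predicting next-year yield

Berry yield responds to the *previous* season as well: carbohydrates
depleted by a heavy crop and nutrients stored from prior fertilization
carry over. The package assembles a lagged panel (each bed-year paired with
the same bed's following year; non-consecutive years never pair; damaged
site-years can be excluded) and fits six nested random-forest regressions
of next-year yield: from composition alone up to composition +
fertilization + current yield + soil test. Folds are grouped by bed so that
no bed appears on both sides of a split — a precaution against
pseudo-replication that ordinary row-wise folds would ignore. R² is the
squared correlation between out-of-fold predictions and observed next-year
yields. Composition enters as ilr coordinates by default (respecting the
simplex geometry); a raw-concentration mode is retained for comparison.

The same machinery classifies next-year yield about the cutoff and builds a
*next-year* reference bank; predictive diagnosis against it reports the
yield a bed could attain next season by rebalancing its current tissue.

## The synthetic survey generator

The original Quebec–Wisconsin survey is not publicly deposited, so the
package ships a generator that emulates the *structure* the analysis
assumes, making every stage testable end to end:

* tissue compositions drawn log-normally around a region-by-cultivar
  optimum anchored on the published across-regions true-negative average,
  with log-scale SDs of 0.08 for macronutrients and 0.35 for
  micronutrients — micronutrients are far more variable than
  macronutrients, as observed in the survey;
* yield decaying with compositional imbalance,
  $Y = Y_{\max}\, m \exp(-(\varepsilon/\tau)^2) + \text{carryover} +
  \text{noise}$, where $\varepsilon$ is the bed's Aitchison distance from
  its optimum, $\tau = 1$ distance unit, $Y_{\max} \sim U(45, 65)$ ton/ha
  per site, and $m \in [0.8, 1.2]$ is a bounded site-level climate/soil
  modifier;
* carryover for years after the first:
  $\beta_{\text{store}}\, z(\text{prior N+K dose}) - \beta_{\text{dep}}\,
  z(\text{prior yield})$ with $\beta_{\text{store}} = 2$ and
  $\beta_{\text{dep}} = 3$ ton/ha per standard deviation (roughly 10 % of
  the mean yield each; fixed standardization constants keep the model
  closed-form checkable);
* Gaussian yield noise with SD 3 ton/ha; defaults of 10 sites × 20 beds ×
  5 years give n = 1000 records.

The Gaussian-decay response and the linear carryover are modelling choices
made for smoothness and analytic checkability, not claims about cranberry
physiology. The generator does **not** emulate real Quebec/Wisconsin
climate normals, soil-series chemistry, or cultivar pedigrees; climate
columns carry no planted yield signal (the site modifier absorbs that
role), years are conditionally independent given the carryover terms, and
the within-bed micronutrient variation is treated as pure noise rather
than split into site-level mineralogy and residual components. Passing
tests on this generator therefore certify the *mechanics* of the pipeline
— closure, log-ratio geometry, bank construction, neighbour search,
ranking, panel assembly, cross-validation protocol — not the survey's
published accuracy figures, which depend on the unavailable data.

`plant_defect()` perturbs one nutrient of a generated record by a known
log-magnitude, re-closes, and re-evaluates the planted yield model; the
test suite uses it to confirm that the diagnosis chain points back at a
known imbalance. Recovery is assessed on balanced (true-negative) beds —
the only beds for which the planted nutrient is the unique ground truth —
with the most factor-specific neighbour filter (same cultivar and region).
With micronutrient background variation at 0.35 log units on both the
diagnosed bed and its reference, a planted |0.5| defect sits near the
detection limit for micronutrients; recovery rates around 0.8 are the
expected ceiling under these conditions, not a software artefact.

## Numerical conventions and problem sizes

* Compositions must sum to 1000 g/kg within 1e-6; clr vectors sum to zero
  within 1e-9; ilr/clr isometry is asserted to 1e-9.
* Balance tolerance for "neither excess nor shortage": |ln ratio| ≤ 0.01
  by default, configurable.
* Distances are displayed at 2 decimal places in reports, with full
  precision preserved in the JSON `raw` block.
* The test suite exercises the stochastic properties at deliberately
  modest problem sizes — n = 1000 records for the classifier checks,
  20 permutation replicates for the null-AUC check, 10 paired seeds of
  6-site × 10-bed × 5-year panels for the carryover variant ordering,
  200 planted defects for recovery — sizes at which the asserted
  qualitative orderings are stable across seeds.

## Known limitations

* The published regional-average distances could not be recomputed exactly
  from the published rounded average row; regional diagnosis therefore
  exposes both averaging conventions instead of asserting either.
* Random-forest regressions of next-year yield have a low R² ceiling on
  synthetic data because next-year compositional imbalance is, by
  construction, unpredictable from current-year features; only the
  *ordering* of the nested variants is meaningful there.
* The classifier's accuracy on synthetic data sits near 0.78–0.81: the
  carryover term depends on prior-year fertilization and yield, which the
  current-year feature set cannot see, adding irreducible label noise near
  the cutoff.
* No fertilizer-dose recommendation engine is included: the pipeline stops
  at ranked shortages/excesses and the attainable yield of the matched
  successful neighbour.
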