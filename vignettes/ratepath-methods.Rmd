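---
title: "Rates of change and causal path models for bacterioplankton communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rates of change and causal path models for bacterioplankton communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratepath)
```

## The scientific problem

Bacterioplankton community metabolism reacts strongly to resource gradients,
but the *pathway* of that reaction is contested: does a community respond by
metabolic adjustment of its existing dominant phylotypes, or by replacing
them with differently equipped taxa?  `ratepath` implements an analysis
chain designed to distinguish these possibilities along *environmental
transitions* — ordered series of sampling sites across the interfaces
between connected aquatic habitats (lake to river, river to marsh), indexed
by the transit time of the water mass.

Six data categories describe each site-date: resources (RES), community
composition from a DGGE-style fingerprint (BCC), single-cell characteristics
(SCC), physiological structure (PS), bacterial abundance (BA) and community
metabolism (BCM).  The chain has three stages:

1. **Rates of change.**  Each multivariate category is normalized,
   standardized and converted to a Euclidean site-dissimilarity matrix.
   For each transition and date, the dissimilarity of every site to the
   transition's head site is regressed on transit time; the OLS slope is
   the category's rate of change (dissimilarity per hour).  BA, a single
   variable, uses the actual abundance difference from the head instead of
   a dissimilarity.  Two further descriptive rates — the change in Shannon
   diversity H' and in presence–absence banding pattern — are reported but
   excluded from path modeling.
2. **Cross-rate regressions.**  Rates are compared across categories with
   log10–log10 OLS regressions (`rate_regression()`), the distance-decay
   style presentation in which a steeper resource gradient should show up
   as faster downstream change.
3. **Path-model selection.**  A library of nine directed acyclic graphs
   over the six rate variables — four *Replacement* structures in which
   RES acts first on BCC, and five *Adjustment* structures in which RES
   acts first on SCC — is fitted to the rate table by recursive
   path analysis, and each structure is tested with a maximum-likelihood
   chi-square statistic.  A structure is *retained* when the test fails to
   reject it.

## The path-model engine

For a recursive system $x = Bx + e$ with acyclic coefficient matrix $B$ and
uncorrelated residuals with diagonal covariance $\Psi$, the implied
covariance is

$$\Sigma(\theta) = (I - B)^{-1}\,\Psi\,(I - B)^{-\top}.$$

All variables are standardized inside the SEM stage, so the entries of $B$
are standardized path coefficients (SD change of the child per SD change of
the parent).  Estimation is equation-wise OLS: each endogenous node is
regressed on its parents, and its residual variance is $1 - R^2$ of that
equation.  For recursive models with diagonal $\Psi$ this equation-wise
solution is the exact maximum of the Wishart likelihood; `ml_fit_numeric()`
verifies the identity numerically (the suite checks agreement to $10^{-6}$
on random 6-node structures).

Model fit uses the ML discrepancy

$$F_{\mathrm{ML}} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p,$$

scaled to $T = (n-1)\,F_{\mathrm{ML}}$ and referred to a chi-square
distribution with

$$\mathrm{df} = \tfrac{p(p+1)}{2} - p - (\text{number of edges}),$$

counting one variance parameter per node (exogenous variance or residual
variance) and one coefficient per edge, with exogenous variables assumed
mutually uncorrelated.  With six variables, every seven-edge structure —
including the canonical accepted models of both scenarios, A-DAG4 and
B-DAG4 — has df = 8.  The $(n-1)$ multiplier is the classical LISREL
convention; it matters mainly for small subsets, which is why subset
analyses skip groups below `min_n` (default 10) rather than fit them
silently.

A caveat worth stating: published chi-square/p pairs in this literature are
not always mutually consistent under a central chi-square reference (a
statistic of 17.9 at df = 8 has p ≈ 0.02, not 0.1), suggesting differing
statistic conventions or resampling-based p-values across software.
`ratepath` reports the standard chi-square p-value and exposes the
statistic, df and n so any alternative reference can be applied downstream.

### The nine-model library

The library ships as JSON (`inst/extdata/dag_library.json`) rather than
code, because prose descriptions of path diagrams rarely pin down every
edge; shipping the encodings as data means they can be amended without
touching the engine.  The constraints the encodings satisfy: every
Replacement model contains RES→BCC and every Adjustment model RES→SCC; RES
has no parents and BCM no children; A-DAG4 and B-DAG4 carry exactly seven
edges (df = 8); B-DAG4 places BCC outside the main RES→SCC→PS→BCM sequence
but linked to both PS and BCM, with an additional BA→BCM path; A-DAG4 routes
RES→BCC into both BA and SCC, both into PS, and PS (plus a weak BA path)
into BCM.  Within those constraints the remaining edges of DAG1–3/5 are the
package's own reconstruction; `build_model_library(path)` loads any
alternative encoding.

## Rate statistics: numerical choices

**Anchor policy.**  The dissimilarity-to-head series of a transition starts
with the deterministic self-comparison (0 h, 0).  Because dissimilarities
are non-negative, anchoring a free-intercept OLS at that exact zero biases
slopes upward whenever the series is dominated by noise: downstream
dissimilarities hover around a positive noise floor while the anchor is
pinned at zero.  In replicate simulations with no resource gradient the
anchored mean resource rate was ~0.05 h⁻¹ against a Monte-Carlo 3·SE of
~0.005, a systematic artefact; without the anchor the mean was within
Monte-Carlo error of zero.  The default policy (`include_anchor = "auto"`)
therefore drops the self-pair whenever at least two downstream sites
remain, and keeps it for 2-site transitions, where the slope is the
finite difference (dissimilarity at site 2)/(transit time) and would
otherwise not exist.  `"always"` and `"never"` are available for
sensitivity analyses.

**Intercept.**  The intercept is left free by default: it absorbs the
noise floor of the dissimilarity measure.  `through_origin = TRUE` forces
the regression through zero for users who prefer the anchored
interpretation.

**Log-log regressions.**  Rates can legitimately be negative (an OLS slope
on noisy dissimilarities), so under `log10 = TRUE` non-positive rates are
excluded — not floored — and the exclusion count is reported
(`n_excluded`).  The SEM stage consumes raw signed rates and standardizes
internally, so the log transform affects only the cross-rate
presentation.

**Standardization.**  z-scores use the sample SD (n−1) and are pooled over
all site-dates of the campaign (one global z-space), because rates must be
comparable across transitions; per-category transform maps
(`log10_shift`) handle right-skewed concentrations before standardization.
Constant variables carry no dissimilarity information and are dropped with
a message; rows with missing values are dropped from that category's
distance matrix with a warning.

**Fingerprint metrics.**  H' uses the natural logarithm by default (the
base is an argument, since fingerprint studies vary), with $0\log 0 = 0$;
band presence uses a configurable intensity threshold defaulting to 0 (any
positive intensity counts), since densitometry detection limits differ
between instruments.

## What the simulator emulates — and what it does not

`simulate_transition_dataset()` reproduces the *statistical* structure the
analysis assumes, at the study's design scale: 13 transitions × 3 sampling
dates (39 rate observations) of 4 sites each, with transit times 0–36 h and
per-transition gradient intensities spanning a geometric ladder from 0.2 to
5 (the field campaign it emulates found transitions differing by orders of
magnitude in gradient steepness).  Within a transition-date, a latent
resource signal rises linearly with transit time at a slope proportional to
the gradient intensity; the other category latents follow the generating
DAG (default: the scenario's canonical 7-edge structure, coefficient 0.7
per edge) with Gaussian site noise (`noise_sd`, default 0.3); observed
variables are fixed-loading projections of their category latent, with
log-normal transforms keeping BA and BCM positive.

Composition is emitted as a band table.  Intensities are a softmax
(concentration-parameterized simplex) over the active band set whose
log-weights drift with the BCC latent — under *adjustment* this changes
only relative intensities, never identities, so presence–absence turnover
to the head site is exactly zero.  Under *replacement* the head's `top_k`
(default 5) dominant bands are progressively swapped for fresh pool
identities; with `turnover_fraction = 1` no dominant band of the head
survives to the terminal site.  `turnover_fraction = 0` degenerates to the
adjustment identity set.

The rate-level sampler `sample_rate_sem()` skips the community layer and
draws the six rates directly from a linear-Gaussian structural model.
Generated nodes use unit residual variance rather than unit total variance:
with all-equal standardized coefficients of 0.6 and three-parent nodes, a
unit-total-variance parameterization would be infeasible (explained
variance above 1), whereas the SEM stage standardizes internally, making
the generating scale irrelevant to the test statistic.

Not modelled: limnological chemistry, seasonal succession, 16S evolution,
gel physics (band co-migration, lane-to-lane alignment error), detection
limits, or spatial autocorrelation between transitions.  Passing tests
therefore demonstrate that the *chain of statistics* behaves as claimed
under its own assumptions — linear responses, Gaussian noise, independent
transition-dates — not that real fingerprint data meet those assumptions.

## Validation performed by the test suite

All problem sizes are the package's own choices, balancing Monte-Carlo
resolution against runtime: estimator equivalence on 50 random recursive
models (n = 250 each); chi-square calibration with 500 replicates of
n = 500 per library model, checked against the 95% binomial band around
0.05; scenario recovery with 200 replicates of n = 2000 (coefficient 0.7),
requiring the generating structure retained and the opposite scenario's
most mismatched structure rejected in ≥95% of replicates; null-gradient
unbiasedness over 100 replicate campaigns; byte-identical artifacts under a
repeated seed.  `scripts/acceptance.R` recomputes headline quantities of
the same kind at slightly reduced replicate counts.

## Known limitations

* Only recursive (feedback-free) models with uncorrelated residuals; no
  latent variables, no RMSEA/CFI/AIC, no d-separation (Shipley C) test.
* Euclidean distance only, matching the method the chain implements;
  Bray-Curtis or Jaccard alternatives would change the meaning of the
  rates.
* The chi-square test's n−1 scaling makes small-subset fits anti-
  conservative; the `min_n` guard is a blunt instrument, not a correction.
* The nine library encodings beyond their stated constraints are
  reconstructions; treat model identity (which DAG number fits) with the
  same caution as any prose-derived encoding, and override the JSON where
  better information exists.
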