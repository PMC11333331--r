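---
title: "Methods: habitat suitability modelling and phytochemical quality zoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat suitability modelling and phytochemical quality zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoniche)
```

# Scope

`phytoniche` links two analyses that are usually run in separate software
stacks: ecological niche modelling of a medicinal plant's distribution, and
chromatographic-fingerprint-based assessment of its phytochemical quality.
The motivating application is *Lonicera japonica* Flos (honeysuckle flower),
whose marker compounds — chlorogenic acid (Ch.a), rutin (Rt), hyperoside
(Hyp), cynaroside (Cyn) and isochlorogenic acid A (Isa A) — vary with the
ecological conditions of the growing region. The package covers the full
chain: raster and occurrence handling, collinearity screening, a
presence-background maximum-entropy model, model evaluation, suitability
zoning and areas, centroid range shifts under climate scenarios, HPLC
fingerprint processing, environment–metabolite regression, and the final
quality-zoning overlay.

# The maximum-entropy distribution model

## Model

Given presence covariate rows $x_1,\dots,x_m$ and a background sample of the
landscape, the model estimates the Gibbs distribution over background cells

$$q(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}{Z(\lambda)}$$

maximizing the L1-penalized average presence log-probability

$$\frac{1}{m}\sum_i \log q(x_i) \;-\; \sum_j \beta_j |\lambda_j|.$$

The features $f_j$ are the canonical classes — linear, quadratic, pairwise
product, and forward/reverse hinge on a fixed knot grid (50 knots per
variable by default) — each scaled to $[0,1]$ on the training data.
Threshold features are omitted: the dense hinge basis spans the same
piecewise-constant responses in the limit, and dropping them keeps the
basis continuous.

Assumptions worth spelling out: presences are an unbiased sample of the
species' occupied environment; the background sample represents the
available environment; covariates are complete at every used cell (any
layer's nodata invalidates the cell).

## Regularization

$\beta_j$ follows the canonical per-class schedule: for
linear/quadratic/product features an interpolation over presence counts
(1.0 at 10, 0.2 at 30, 0.05 at 100 or more), for hinge features the
constant 0.5, each scaled by $\sqrt{s_j^2/m}$ with $s_j^2$ the feature
variance over presences, and by the user's `regMultiplier`. As the
multiplier grows all weights shrink to zero and the gain to zero (tested).

## Optimization and numerical choices

The objective is concave, so the optimizer cannot change the optimum. We
use proximal (soft-threshold) gradient ascent with a backtracking line
search and an adaptively doubled step. Two stopping modes exist:

* `tol > 0` (default `1e-5`, the conventional setting): stop when the gain
  improvement falls below `tol`, after at most `maxIter` (default 500)
  iterations.
* `tol = 0`: iterate until the weight update itself stalls. This exists
  because the objective is flat to double precision well before $\lambda$
  stops moving; the gradient is computed to full precision, so weight
  accuracy of $10^{-7}$ or better is reachable even though no measurable
  gain change remains. The test suite uses this mode to compare a
  single-feature fit against a brute-force one-dimensional optimizer.

The line search accepts only non-decreasing objectives, which makes the
gain trajectory monotone by construction (asserted after every fit, along
with $\sum_{bg} q = 1$ to $10^{-9}$).

Presence rows are appended to the normalization background by default (the
usual "samples added to background" convention); `addSamples = FALSE`
switches it off.

## Logistic output

Reported suitability uses the entropy-based logistic transform
$p = e^H q / (1 + e^H q)$, where $H$ is the entropy of the fitted
distribution — the standard output of maximum-entropy distribution
software with $\tau = 0.5$. A uniform model gives $p = 0.5$ everywhere,
and the transform is strictly monotone in $q$, so rankings (and hence AUC)
are identical between raw and logistic outputs.

## Evaluation

* **AUC** is the Mann–Whitney pair-counting estimate with ties counted one
  half, computed via midranks (exactly the exhaustive pair count).
* **Contributions** attribute each iteration's gain increase across
  features in proportion to $|\Delta\lambda_j \cdot \nabla_j|$, products
  split evenly between their two variables, normalized to 100%. With a
  full-gradient optimizer this is the natural generalization of the usual
  per-update attribution; a single-variable model receives 100% and two
  equally informative variables split near 50/50 (tested with 10-point
  tolerance).
* **Permutation importance** permutes one variable across presence and
  background jointly, recomputes the training AUC without refitting, and
  normalizes the drops to 100%. One permutation per variable by default,
  seedable; tests use more for stability.
* **Jackknife gains** refit with-only and without models per variable; the
  reported training gain is
  $\frac{1}{m}\sum_i \log q(x_i) + \ln n_{\text{norm}}$, zero for an
  uninformative model.
* **Response curves** are marginal: the target variable sweeps its observed
  range while all others sit at their background means, and the first/last
  values with $p$ above a reporting threshold (default 0.55) ride along as
  an attribute.

# Zoning, areas and centroids

Suitability grades use the four-class scheme with fixed edges 0.2/0.4/0.6
by default — the printed grade boundaries of the motivating study — with
Fisher–Jenks natural breaks available (`jenksBreaks`, an exact dynamic
program verified against exhaustive partition search at small n). Intervals
are left-closed/right-open except the last: a cell exactly on a break
belongs to the upper class. This choice is logged in outputs; the study's
text writes contiguous intervals without fixing the convention.

Cell areas use a spherical Earth of radius $R = 6371$ km:
$((\pi R/180)\cdot\text{cellsize})^2\cos\phi$ at row-center latitude
$\phi$. The same radius drives the haversine distance, because it
reproduces all four mutually consistent published centroid-migration
distances to the printed 0.01 km. Migration distances are measured from
the *current* centroid to each scenario centroid, not chained between
periods — the only reading consistent with those published values.

The total-suitable binarization threshold defaults to $p \ge 0.04$ as
printed in the source method description. That value is plausibly a typo
for 0.4; it is therefore a configuration value rather than a constant, and
the default keeps the printed number. Centroids weight cells by true
(cosine-corrected) area; an unweighted mode exists for comparison.

# Fingerprint processing

Peak detection finds local maxima above a height threshold whose
prominence over the flanking valleys exceeds a second threshold; bounds
sit at the valleys and the area is the trapezoidal integral above the
straight baseline between them. Retention-time correction is
piecewise-linear through anchor peaks (greedy nearest-within-tolerance
matches to the reference sample; the identified marker peaks are the
recommended anchors), and only columns occupied in every sample become
common peaks. Correction moves times, never areas (tested).

Similarity is the congruence (cosine) coefficient on common-peak area
vectors — the convention of the standard pharmacopoeia similarity software
— with Pearson correlation available as the usual alternative. Whether the
original analysis used area vectors or full digitized curves is not
stated; area vectors are the default here. RSDs use the sample (n−1)
standard deviation, the method-validation convention. Quantification is
one-point external standard with the extraction defaults of 1.0 g powder
in 50 mL solvent.

# Environment–metabolite models and quality zoning

Per-compound stepwise OLS (forward/backward/both, AIC or BIC via
`stats::step`) selects ecological factors; the bivariate correlation table
(Pearson r, two-sided t-test p, stars at 0.05/0.01) accompanies it because
the source describes both routes without stating which produced the final
surfaces — both are provided. Content surfaces are cell-wise linear
predictions floored at zero (with a flag count).

The study never states how several content surfaces combine into one
quality map. We min–max normalize each content raster over the masked
region (suitability at or above 0.2, i.e. above "no suitability") and take
the unweighted mean, with per-compound weights exposed; this is flagged as
an interpretation in the provenance of every zoning map. A constant
(degenerate) content raster contributes the neutral score 0.5, logged.
Cyn is excluded from the default pipeline zoning, mirroring the source's
decision to drop it for lack of clear correlation. Grades come from Jenks
on the scores (default 4 classes); the nodata pattern of the zoning map is
exactly the complement of the suitability mask (tested).

# The synthetic scene: what it emulates and what it does not

All stages are exercised on generated data with known truth:

* **Environmental layers** are standardized Gaussian random fields
  (spectral synthesis, correlation length 8 cells) mixed through the
  Cholesky factor of a target correlation matrix. The default scene has 7
  layers named after the retained factors of the motivating study, with
  one pair correlated at 0.85 so collinearity screening has real work.
* **Occurrences** (298 by default, the study's record count) are drawn
  with replacement from valid cells with probability proportional to
  $\mathrm{logistic}(\beta x + b_0)$, jittered within the cell. The default
  law — weights 3 on `bio6` and 1.2 on `bio12`, intercept $-6$ — puts
  about 6% of the landscape at high suitability, matching the
  range-restricted situation of the study species (its high-suitability
  share of the national land area is about 6%), and yields an oracle
  discriminability near the published model's AUC of ~0.89. These are
  scene parameters chosen once to emulate the study conditions.
* **Chromatograms** plant 21 shared Gaussian peaks (the study's common-peak
  count) across 11 samples (its region count) over a 50-minute run, with
  lognormal between-sample area variation, linear drift, white noise and a
  few per-sample spurious peaks. A spread of 0.25 approximates the
  region-to-region similarity range seen in real panels (0.82–0.99); the
  low-noise validation scene uses 0.1.
* **Contents** follow a linear law in chosen factors plus Gaussian noise,
  floored at zero.

What the synthetic scene does **not** emulate: real bioclimatic marginal
distributions and units, spatial sampling bias in herbarium records,
non-square grids with coastline-shaped nodata, chromatographic peak
tailing and co-elution, and spatial autocorrelation of residual content
variation. Passing the recovery tests therefore demonstrates correctness
of the machinery, not performance claims about any real landscape.

Problem sizes in the tests and the acceptance script — 64×64 to 80×80
grids, 1,000–2,000 background cells, about a dozen bootstrap replicates,
8–10 hinge knots in heavy loops — are the package's standard small-scene
settings; they keep every fit well-conditioned while the whole suite runs
in well under a minute on a laptop core. Full-size settings (10,000
background points, 100 replicates, 500 iterations, 50 knots) remain the
defaults of `defaultPipelineConfig()`.

# Known limitations

* No reprojection or resampling: all layers must already share one grid.
* No clamping or extrapolation diagnostics (MESS-style maps) for
  prediction outside the training range; linear features extrapolate.
* No categorical features and no cloglog output.
* The Jenks dynamic program is $O(kn^2)$ and subsamples above 5,000
  values (deterministically, from the sorted vector).
* Quality zoning inherits every caveat of the linear content models; no
  geostatistical interpolation is attempted.
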