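---
title: "Methods: canal morphometry, section geometry, and phylogenetic scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canal morphometry, section geometry, and phylogenetic scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbone)
```

# The question the pipeline answers

Laminar bone — primary bone whose vascular canals run predominantly
circumferentially around the shaft — has been read as a signature of
habitual torsional loading in the wing bones of flying vertebrates.
`wingbone` implements the full measurement chain needed to test that idea
quantitatively in bats and birds: classify the primary vascular canals of a
transverse humeral section and estimate the laminarity index (LI); compute
the cross-sectional geometry that summarizes torsional rigidity (the polar
section modulus `Zp`); derive size-standardized growth and metabolic rates;
and fit allometric log–log regressions that account for phylogenetic
non-independence. Every stage can run on synthetic data with known ground
truth, so the pipeline's error budget is measurable.

# Canal morphometry

## Orientation criteria

A canal is reduced to two numbers: the aspect ratio `a/b` of the ellipse
matched to its cross section, and the acute angle `theta` between the
ellipse's major axis and the local periosteal tangent, folded into
\[0°, 90°\]. The four-way classification is applied in a fixed order:

1. aspect ratio < 3 → **longitudinal** (the canal pierces the section
   nearly end-on, so its in-plane outline is roundish);
2. `theta` in \[0°, 22.5°\] → **circumferential**;
3. `theta` in \[67.5°, 90°\] → **radial**;
4. anything else → **oblique**.

The aspect test is strict (`< 3`) and applied first; the angle bands are
closed so the `±22.5°` notation is inclusive. The boundary set has measure
zero for continuous measurements, but the tie-break still has to be fixed
for the classifier to be a total partition — the tests verify the partition
against a brute-force restatement on a dense grid.

## Straightening and its validation

The periosteal tangent varies around a curved cortex, so each cortical
octant (a 45° sector about the section centroid, centred on an anatomical
axis; the four diagonal octants are not measured) is *uncurved* before
measurement: the octant is resampled into a frame whose horizontal axis is
arc length along the smoothed periosteal contour and whose vertical axis is
depth along the inward normal. The periosteal surface then maps to the top
row and becomes a constant angular reference.

Numerical choices, in order of appearance:

* **Contour extraction** is radial ray casting at 0.05° steps; ring-like
  sections are star-convex about their centroid so this is exact up to
  pixel quantization.
* **Smoothing** is a moving average applied twice (before and after
  arc-length resampling) with a 24 px window (about 50 µm at the 2.1 µm/px
  montage resolution), reflected at the segment ends and capped at a
  quarter of the segment length. Unsmoothed rasters give tangent noise of
  several degrees; the double pass brings it under ~1°.
* **Sampling** is bilinear at 1 px steps. A fold-over gate rejects the
  transform when the contour's curvature radius is smaller than the
  sampled depth.
* **Validation** re-implements the test-overlay idea: known angles and
  circles are drawn in the original frame, pushed through the map, and
  remeasured. Gentle curvature (curvature radius ≥ 10× cortical thickness)
  keeps angle deviations ≤ 5° and circle aspect ratios within 1.00–1.17;
  the report flags anything beyond those gates.

The transform has one *systematic* distortion: at depth `d` below a surface
with curvature `kappa`, tangential distances are stretched by
`1/(1 - kappa d)`, which biases measured angles toward the tangent and
perturbs aspect ratios by up to ~10% in the gently curved regime. Because
`kappa(s)` is known from the smoothed contour, the measurement step undoes
it: each canal region's tangential offsets are rescaled by the local metric
before the ellipse fit (curvature compensation). This is a deliberate
refinement over measuring the raw straightened raster; it removes the
systematic part of the class-boundary error, leaving only pixel noise.

## Ellipse fitting and branched canals

Canal regions are 8-connected components of the canal mask. Regions under
5 px are dropped (with a logged count) — the moment fit is unstable below
that size. Each remaining region gets the moment-matched ellipse: centroid,
axes `4*sqrt(eigenvalues)` of the second-moment matrix (with the 1/12
per-pixel term), and principal-axis angle. Branched canals are split at
skeleton junctions: Zhang–Suen thinning, junction candidates where a
skeleton pixel has ≥ 3 skeleton neighbours, a one-pixel dilation cut, and a
decision rule that requires at least three substantial arms (≥ 5 px and ≥
25% of the longest arm) before splitting — thinning artifacts (staircase
doubling, end spurs) otherwise masquerade as junctions. Region pixels are
assigned to the nearest arm, so the pixel union is preserved.

## The laminarity index

LI is the proportion of circumferential canals among primary canals
(secondary-osteon canals are excluded upstream). Counts are small — an
octant may hold a handful of canals — so the package reports the Wilson
score estimate
`p~ = (x + z²/2) / (n + z²)` with interval half-width
`[z/(n + z²)] * sqrt(x(n−x)/n + z²/4)`,
which shrinks away from 0 and 1 and never leaves \[0, 1\]. The "plus-four"
simplification is available as an option. Conventions at the edges: a
section with primary canals but none circumferential has LI exactly 0 and
no interval; a section with no measurable primary canals has LI undefined
(`NA`), mirroring the "n/a" entries of published specimen tables. Published
tables do not state which convention they used for every entry, so both
are exposed; the estimate, both bounds, and the half-width are all
reported because printed "(95%CI)" columns are ambiguous between the two.

```{r wilson}
laminarity_index(5, 20)
```

# Cross-sectional geometry

A cortical profile is a binary mask (cortex white). Areas and moments use
the midpoint rule — each foreground pixel contributes its full area at its
centre — which converges at first order and is testable against closed
forms; at ≥ 1024 px across the section every quantity is within 1% of the
analytic value for annuli, ellipses, and offset-hole sections:

* `CA` — cortical area; `TA` — area inside the periosteal boundary
  (cavity included), obtained by flood-filling the background from the
  image border;
* `Imax >= Imin` — eigenvalues of the second-moment tensor about the area
  centroid; `J = Imax + Imin` holds exactly by construction
  (perpendicular-axis identity);
* `Zp = J / r_max`, with `r_max` the maximum centroid-to-periosteal
  distance. The extreme-fibre radius is the standard section-modulus
  moment arm; the mean periosteal radius is available as an option since
  published work does not always state the choice.
* The shape ratio `Imax/Imin` gauges circularity; above 1.5 (configurable)
  a caution is logged because `Zp` is only a heuristic for strongly
  elliptical sections. Values are never altered by the caution.

# Growth and metabolic standardization

Growth curves are the three standard sigmoids in mass form. At the
inflection:

| model | inflection mass | maximum rate | RGR = rate/mass |
|---|---|---|---|
| logistic | `A/2` | `KA/4` | `K/2` |
| Gompertz | `A/e` | `KA/e` | `K` |
| von Bertalanffy (cubed) | `8A/27` | `4KA/9` | `3K/2` |

These closed forms are verified in the tests by numerical differentiation
of the curves. The relative growth rate is independent of the asymptote
`A`, which is the point of the standardization; mass-specific field
metabolic rate is `FMR/mass`. Log10 transforms are applied after
standardization, never before. Curve fitting (for the synthetic path;
compiled literature parameters are used as-is) is Levenberg–Marquardt
nonlinear least squares with a small multi-start grid over `K` and `t0`
because the initial Jacobian of the cubed von Bertalanffy form can be
near-singular at a single heuristic start.

# Phylogenetically informed scaling

All scaling fits are model-I simple linear regressions of log10-response on
log10-predictor. Model II (reduced major axis) is deliberately not offered:
without within-species replication to estimate error variances it tends to
overcorrect.

* **OLS** is generalized least squares with an identity structure — the
  implementation is a single code path, and the tests require exact
  equality with `lm()`.
* **PGLS-BM** uses the Brownian variance–covariance matrix (shared
  root-to-MRCA branch length).
* **PGLS-OU** uses the Martins–Hansen stationary correlation
  `exp(-alpha d_ij)` on patristic distances. `alpha = 0` degenerates to an
  all-ones matrix (flagged); large `alpha` collapses to the identity, so
  PGLS-OU reproduces OLS exactly in the limit — a useful internal
  consistency check that the tests enforce to `1e-6` on the slope.
  Published analyses report fits at stated `alpha` values without saying
  how they were chosen, so the default mode fits at user-supplied values
  (`k = 3` parameters for AICc); REML profiling of `alpha` is available
  (`alpha = "profile"`, `k = 4`).

Fitting maximizes the *restricted* log-likelihood (REML) by default.
Because all candidate models share the same fixed-effects design matrix,
REML likelihoods are comparable across them and AICc
(`-2 logLik + 2k + 2k(k+1)/(n-k-1)`) is valid for selection; ML is
available behind a flag. Confidence intervals are Wald-t with `n - 2`
degrees of freedom under every structure — the published tables do not
state their CI construction, and with the correlation structure treated as
known the t-interval is exact (the acceptance suite checks 93–97% coverage
of a known slope over 500 Brownian simulations). Polytomies are resolved
into zero-length branches before any covariance is built; if that makes the
covariance computationally singular, a ridge of `1e-10 × mean(diag)` is
added with a message.

Model choice follows three ordered criteria: (1) if the response shows no
significant phylogenetic signal — Blomberg's K with a tip-permutation test
of the phylogenetically corrected mean squared error, 999 permutations,
threshold p < 0.05 (the published workflow states the gate but not the
threshold or replicate count; these are this package's defaults, exposed as
arguments) — the OLS fit is selected outright; (2) fits whose residuals
fail a two-sided runs test (exact run-count distribution for n ≤ 40,
normal approximation beyond; signs ordered by fitted value; "random" means
p ≥ 0.05) are discarded — this operationalizes the visual residual-plot
inspection and is advisory and configurable; (3) the survivor with the
lowest AICc wins. If everything is eliminated the OLS fit is returned with
a warning, and the full decision trace is kept.

```{r scaling}
sim <- simulate_scaling_dataset(24, trait_model = "BM", sigma2 = 0.08,
                                slope = -0.35, intercept = 1, seed = 31)
out <- run_scaling_analysis(sim$traits, sim$tree, alpha = c(0.5, 2), seed = 7)
out$selection$trace
```

# What the synthetic generators emulate

* `simulate_canal_field()` builds an annular cortex populated with
  elliptical canals whose angles are drawn *relative to the local
  periosteal tangent*, so truth labels are exact under the classifier's own
  convention: circumferential and radial canals uniform in their closed
  ±22.5° bands, oblique uniform in the open (22.5°, 67.5°) band,
  longitudinal with aspect uniform in \[1, 3) and arbitrary angle. Defaults
  — 2.1 µm/px, outer radius 2000 µm, thickness 200 µm (curvature radius
  10× thickness, i.e. the gently curved regime the deformation gates
  certify), major axes 30–55 µm, non-longitudinal aspect 3.2–6 — are fixed
  study conditions, not tuning knobs. Canals are non-overlapping by
  rejection sampling.
* `generate_cortical_profile()` rasterizes annuli/ellipses/offset-hole
  sections and attaches *closed-form* geometry computed from the shape
  parameters, never from the raster, so raster convergence is testable.
* `generate_growth_series()` evaluates a chosen sigmoid exactly and adds
  i.i.d. Gaussian noise.
* `simulate_scaling_dataset()` grows a pure-birth tree (rescaled to unit
  depth so `alpha` and `sigma2` are dimensionless), draws the predictor
  uniformly, and adds multivariate-normal residuals with covariance
  `sigma2 * V_BM` or `sigma2 * exp(-alpha d)` about the true line.

What they do **not** emulate: secondary remodeling and osteon exclusion
(canal records arrive pre-labelled primary/secondary), staining appearance,
real canal shape irregularity, measurement error in specimen masses, or
non-ultrametric trees. Passing tests therefore certify the measurement and
inference chain, not the upstream histology.

All generators take an integer seed, are bit-reproducible, and restore the
caller's RNG state.

# Problem sizes and runtime envelope

The test-suite sizes are the package's chosen calibration conditions:
200-canal fields at 2.1 µm/px for end-to-end recovery (target ≥ 95%
true-class recovery; misclassification comes only from raster/transform
noise at the class boundaries); 1024 px sections for the 1% geometry
tolerance; 500 Brownian simulations at 64 tips for CI coverage; 200
replicates for the K calibration (median within \[0.8, 1.2\]); 4000
Monte-Carlo draws for the residual-covariance check of the trait
simulator.

# Known limitations

* Published specimen tables print rounded measurements (integer grams and
  millimetres); regressions recomputed from them can differ from
  regressions fit on the original unrounded data in the second or third
  decimal of slope and intercept. The packaged specimen table is treated
  as a fixture of printed values.
* The growth/metabolic compilations and pruned supertrees used in the
  published scaling tables are external supplementary files; the package
  ships the ingestion schema and a documented drop-in slot
  (`inst/extdata/supplementary/`) rather than the data.
* Laminarity "n/a" vs "0" conventions in published tables are not fully
  specified; the `n_total = 0` rule implemented here is one reasonable
  reading.
* `Zp` from masks assumes a near-circular section; the shape-ratio caution
  is advisory only.
* The straightening contour tracer assumes ring-like, star-convex sections
  about their centroid; strongly lobed cortices would need a boundary
  tracer rather than ray casting.
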