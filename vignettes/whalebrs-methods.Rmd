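---
title: "Methods: shore-based behavioral dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shore-based behavioral dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`whalebrs` implements the analysis chain of a shore-based behavioral
response study (BRS) of baleen whales exposed to industrial underwater
sound: theodolite tracking from coastal stations, movement and respiration
response variables over fixed bins, per-bin acoustic and vessel covariates,
and weighted correlated-residual regression of responses on "natural" and
"impact" explanatory variables. Because raw field datasets of this kind are
rarely public, the package also ships a complete synthetic-data generator
with known ground truth; every statistical guarantee the pipeline relies on
is validated against that truth in the test suite.

## Geolocation from theodolite angles

A theodolite on a station of surveyed height \(h\) measures a depression
angle \(\theta\) below the true horizontal and a horizontal-circle angle. On
a spherical earth of effective radius \(R_e = R/(1-k)\) (refraction
coefficient \(k = 0.13\) by default, the standard terrestrial value), the
ground arc \(D\) to a sea-surface target satisfies

\[\tan\theta \;=\; \frac{(R_e+h) - R_e\cos(D/R_e)}{R_e\,\sin(D/R_e)},\]

which the package solves in closed form through the sine rule
(`declination_to_range()`), with the exact inverse used by the observation
simulator. The flat-earth limit \(D = h/\tan\theta\) is recovered as
\(R_e \to \infty\); the curvature term is material beyond roughly 3 km (at
5 km range and 20 m height it exceeds 500 m). The effective height is
station height minus tide, so a rising tide strictly increases the range
inferred for a fixed angle. Angles at or below the horizon dip
\(\arccos\!\big(R_e/(R_e+h)\big)\) are rejected rather than extrapolated.

All positions live on a local planar grid (km east/north) anchored at the
station; at the sub-50-km extents of shore-based tracking the planar error
is orders of magnitude below instrument noise (5 arc-sec class theodolites
scatter a 5-km fix by ~30 m radially at 20 m height).

## Response variables

Raw fixes are resampled by linear interpolation at exact 90-s epochs
(`resample_track()`), splitting at raw gaps above 600 s; interpolation
never extrapolates. Ten geometric movement variables are computed on
consecutive, non-overlapping bins of 7 steps (10.5 min, 8 positions):
speed, linearity (net/cumulative displacement), reorientation rate (total
absolute heading change per minute), mean resultant length of headings
("mean direction") and of turning angles ("directionality"), range index,
distance from shore, the cosine and sine of net-movement azimuth, and the
relative orientation of movement to the closest vessel and closest seismic
vessel (ROW, 0° = toward, 180° = away). Non-overlapping bins avoid
induced autocorrelation beyond what the residual model handles. The range
index is defined here as the maximum pairwise distance among the bin's
eight positions — a definition choice, stated because field protocols vary;
the directionality index is the mean resultant length of turning angles,
distinguishing it from mean direction (resultant of headings). Zero net
displacement leaves the direction variables missing while linearity is
kept at 0.

Respiration metrics derive from focal-follow event streams. A surfacing is
a maximal run of blows with inter-blow gaps at or below 60 s (configurable)
not split by a recorded dive-start; dives are the intervals between
surfacings. The seven binned variables are the mean inter-blow
(respiration) interval, mean surface and dive durations, blows per
surfacing, surface blow rate, dive-surface blow rate, and percent time at
surface. Cycles attach to the bin containing their midpoint; a bin with no
complete cycle is missing, never zero-filled, and a bin whose surfacings
are all single blows has an undefined (missing) surface blow rate. First
three principal-component scores of the movement and of the respiration
variable sets (correlation-matrix PCA, dominant loading oriented positive)
are carried as additional responses.

## Exposure and covariates

The parametric sound field propagates each source as
\(RL(r) = SL - N\log_{10} r - \alpha r\) with defaults \(N = 20\) and
\(\alpha = 1\) dB/km, and a seismic source level of 226 dB re 1 μPa²·s
per shot at 1 m: received per-shot levels then run from ~171 dB at 0.5 km
to ~82 dB at 50 km, inside the 53–172 dB envelope such surveys produce at
whale positions, with vessel (continuous) sources at 185 dB per 30-s
window. Multi-source and multi-shot exposure combines on the energy scale,
\(10\log_{10}\sum 10^{L_i/10}\). Along each track, SEL is evaluated every
30 s; the per-bin acoustic covariate is the energy mean of the bin's
21 steps (the mean preserves additivity with cSEL; a max summary is
available by option), and cumulative SEL restarts at track — never bin —
boundaries. Seismic and vessel channels stay separate throughout; a
pile-driving channel exists in the types but is excluded from default
models. Vessel covariates are the bin-minimum distances to the closest
vessel and closest seismic vessel, the vessel count, and ROW at the bin
midpoint.

## Prey interpolation

Benthic biomass at whale locations is interpolated two ways: IDW (power 2,
12 nearest neighbours) and regression kriging — an ordinary-least-squares
depth trend plus ordinary kriging of the residuals under an exponential
variogram fitted by Cressie-weighted least squares on the empirical
variogram, with zero nugget by default so both interpolators reproduce
sample values exactly. No installed geostatistics library provides this
combination, so the kriging system is assembled and solved directly; tests
verify predictions against an independently constructed solve and recover
simulated depth trends and variogram ranges. Per-bin prey covariates take
the maximum interpolated biomass over the bin's eight positions, restricted
to the sub-20-m sampling domain; biomass differences among behavior states
are compared by one-way ANOVA with a state-by-taxon median table. Prey
biomass is not a default model covariate (its apparent effects are largely
depth covariance); it can be added explicitly.

## Response models

Each response is transformed toward normality: logit for [0, 1] indices
(with the boundary squeeze \(x \to (x(n-1)+0.5)/n\)), natural log for
speed, distances and respiration variables, cosine/sine for directions.
Continuous covariates are screened pairwise at |r| > 0.60; among
collinear acoustic metrics the SEL-based pair (SEL_30s, cSEL) is retained
by preference.

The fit itself (`brs_model()`) is weighted generalized least squares with
within-track residual correlation — AR1 over the bin sequence (default),
compound symmetry, unstructured, or none — estimated by REML via `nlme`,
with an optional track-level random intercept (then `nlme::lme`). The
"GEE with lme" phrasing in field reports is internally contradictory;
this package implements it as weighted GLS/LME with selectable correlation
structures compared by BIC, which matches the stated structures and
software lineage. Pseudo-replication from unequal track lengths is
countered by Horvitz–Thompson-style weights \(w_{ij} = N/(J n_j)\): every
track carries equal total mass and the weights sum to the bin count; the
exact normalization is a package decision since only proportionality is
ever stated in the field literature. Stepwise selection minimizes
ML-estimated BIC, offering natural covariates before impact covariates,
with a backward pass and ties (< 0.01) resolved toward the smaller model;
the selected model is refit by REML. No multiple-testing correction is
applied; significance is flagged at raw p < 0.05, matching how such
coefficient tables are conventionally reported. Time of day enters as
continuous hours by default (a cyclic encoding is a one-line transform
away). Missing rows are deleted listwise per model with counts recorded.

## The synthetic generator and what it does (not) show

`sim_config()` fixes the study conditions: four behavior states (feeding,
feeding/traveling, traveling, mixed) switching as a Markov chain whose
default stationary distribution (26/33/30/11%) mirrors a foraging-season
activity budget; log-normal per-state speeds (1, 2, 4, 1.5 km/h means) and
wrapped-normal turning angles (60°, 30°, 10°, 45°); gamma dives (means
280, 200, 150, 180 s), 1 + Poisson blows per surfacing and gamma
inter-blow intervals (14, 17, 22, 18 s) — feeding dives long and
respiration intervals short, the benthic-forager pattern. Seismic vessels
acquire parallel lines at 4.5 kn with 10-s shots; a support vessel follows
random waypoints; stations sit at 10.8–23.7 m with one fix per surfacing
and 5 arc-sec angular noise; tide is sinusoidal and depth grows 2 m/km
offshore. A dose-response effect can be injected with known slope:
log-speed (or heading away from the source, or log inter-blow interval)
shifted linearly in the SEL excess above a threshold.

The generator emulates the statistical structure the analysis assumes —
state-dependent movement/respiration regimes, distance-decaying exposure,
serially correlated bins — not the physics of real propagation (no
bathymetric ducting), observer fatigue and sighting-probability gradients,
prey-driven habitat selection, or mother-calf classes. Passing tests
therefore demonstrate that the pipeline recovers what it is pointed at
under its own assumptions, not that any particular field dataset satisfies
those assumptions.

## Validation scales and numerical choices

The test suite validates, at scales chosen to keep a laptop run short:
geodesy round trips below 1 m over 1000 random height/range cases;
equality of all movement and respiration metrics with independent
brute-force references to 1e-9 relative over 1000/300 random cases; cSEL
closed forms to 1e-9 dB and monotonicity; IDW/kriging exactness and
agreement with direct linear solves to 1e-8; type-I error of the impact
coefficient within [0.03, 0.08] over 500 null replicates (50 tracks of
8–12 bins each, AR1 ρ = 0.3); 95% CI coverage of an injected slope in at
least 90 of 100 replicates; BIC preference for AR1 on ρ = 0.5 residuals in
at least 95 of 100; stepwise retention of the null model in at least 90%
of 200 all-noise replicates and selection of a standardized-effect-1
predictor in 100 of 100; end-to-end bit-determinism by seed; and the
qualitative field patterns (feeding dives longer, respiration intervals
shorter, one-sided α = 0.01; injected avoidance yielding a significant
negative closest-seismic-vessel-distance coefficient). The avoidance
scenario uses a 140-dB threshold so the response is spatially localized
around the source line — a uniform, always-on effect would leave the
distance term with no contrast to estimate.

Numerical notes: energy sums factor out the peak level before
exponentiating; the kriging system is ridge-stabilized on singularity (with
a warning) and the variogram fit falls back to moment-based defaults if the
optimizer fails; GLS fits fall back along unstructured → constant → none on
non-convergence, recording the fallback; pipeline CSVs print doubles at 17
significant digits so cached stages round-trip losslessly.

## Known limitations

Positions come from single-station geodesy (no multi-station fusion);
behavior states are taken from field annotation, not inferred from
movement; the unstructured correlation option is practical only for short,
balanced tracks; HT weighting is interpreted as variance weighting inside
GLS, which is the conventional compromise when case weights meet
correlated residuals; and dose-response threshold estimation (finding the
exposure level at which responses begin) is deliberately out of scope — the
models here estimate linear associations on the measured exposure scale.
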