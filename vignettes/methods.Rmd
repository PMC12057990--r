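---
title: "Reconstructing pastoral mobility from tooth-enamel isotopes: models and design"
author: "isoMobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pastoral mobility from tooth-enamel isotopes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoMobility)
```

## The problem

Mobile pastoralists move their herds between seasonal camps, and a
grazing animal's tooth enamel writes a chronological record of those
moves. Hypsodont (high-crowned) molars mineralize over one to several
years; enamel, once mature, is never remodelled, so isotope values
sampled sequentially along the crown — from the occlusal surface down to
the enamel-root junction (ERJ) — form a time series of the animal's
first years of life. Three systems carry complementary signals:

* **⁸⁷Sr/⁸⁶Sr** tracks the bioavailable strontium of the underlying
  geology, so it fingerprints *where* the animal fed;
* **δ¹⁸O** follows the seasonal cycle of meteoric water (high in
  summer, low in winter), providing the *clock*;
* **δ¹³C** responds to the C₃/C₄ composition of forage, which in
  mountain steppe varies with *elevation*.

`isoMobility` implements the full inference chain from raw measurement
to mobility statement: laser-ablation transect reduction, isoscape
modelling with spatial uncertainty, Bayesian geographic assignment,
seasonal anchoring, elevation inversion, relocation counting, and a
single-phase radiocarbon chronology, together with a forward model
(GPS track → predicted profile) and synthetic generators that give
every stage a known ground truth.

## Signal reduction

Laser-ablation MC-ICP-MS transects report ion-beam intensities at
masses 88–83. `correctInterferences()` strips ⁸⁷Rb from mass 87 using
the interference-free ⁸⁵Rb beam and the natural ⁸⁷Rb/⁸⁵Rb abundance
ratio, and plasma-gas krypton from masses 86 and 84 using ⁸³Kr. The
abundance constants are configuration (`naturalRatios()`), not
hard-wired, since reported constants differ slightly across
laboratories. No exponential mass-bias law is applied by default:
bracketing against a certified solid standard
(`bracketNormalize()`) is the only normalization beyond interference
stripping. Each standard measurement yields a factor
certified/measured; sample points receive the position-weighted linear
interpolation of the flanking factors (a sample midway between
brackets gets their average), with a nearest-standard fallback and
warning outside the flanked range.

Profiles are then smoothed with a centered moving average and moving
SD over 35 consecutive measurements (`rollingSmooth()`), about 2 mm of
transect at typical spot spacing. Windows shrink at the profile ends
rather than dropping points: discarding 17 samples per end would
throw away several millimetres of crown record. The rolling SD mirrors
the mean's truncation — the two must stay aligned because the
assignment consumes both at the same positions.

## The isoscape

`fitIsoscape()` models site-level bioavailable ⁸⁷Sr/⁸⁶Sr as a random
forest over gridded covariates (lithological age and composition,
climate, deposition, …), 3000 trees by default, evaluated by ten-fold
cross-validation. Before fitting, `filterCorrelated()` removes
features with |Pearson r| > 0.9 (absolute value: a strongly
*negatively* correlated pair is just as redundant), keeping the
earlier-listed member for order stability, and `selectVariables()`
performs noise-thresholded permutation-importance selection: candidate
features must beat the best of several appended pure-noise probes in a
majority of repeated forests *and* retain a non-negligible share
(≥ 1%) of the top importance. The relative floor matters because a
noise probe can never flag a candidate's fixed in-sample spurious
correlation — only its magnitude can. This single-stage procedure
replaces multi-stage wrappers; the contract downstream is only that
the most relevant predictors survive.

Spatial uncertainty comes from the same forest's quantile predictions:
the SD layer is the half-width of the central 68.27% prediction
interval, σ ≈ (q₀.₈₄₁₃ − q₀.₁₅₈₇)/2, which reduces to the residual SD
under Gaussian noise. On a synthetic field with homoscedastic
σ = 0.001 this calibrates to within ~20–30%, slightly conservative —
quantile forests widen intervals where the mean is locally biased.
Cross-validation folds are site-random, not spatially blocked; with
strong spatial autocorrelation in real covariates this flatters the
CV score, which is why `validatePoints()` exists for genuinely
held-out samples.

Grids are planar metric (cell size in metres, lower-left origin,
half-open cell membership) and are written as ESRI ASCII rasters —
a plain-text exchange format any GIS reads — in mean/SD pairs.

## Geographic assignment

For a profile feature with smoothed mean m and rolling SD s,
`posteriorSurface()` computes, per cell i of the assignment box, the
normal likelihood of m at the cell mean μᵢ with variance σᵢ² + s²:
the isoscape's spatial uncertainty and the sample's own uncertainty
in quadrature, since the two error sources are independent. The prior
is uniform over the box; the posterior is the normalized likelihood.
`topArea()` extracts the top 10% *of the valid cell count* — an area
threshold, matching standard practice in continuous-surface
assignment, not a 10% cumulative-probability threshold; ties break by
fixed cell index so the mask is reproducible. `nestedAssignment()`
repeats the surface at 100, 200 and 400 km boxes centred on the site,
because probability of origin is always relative to the area under
consideration.

Feature choice (peaks, troughs, plateaus) is automated as local
extrema of the smoothed profile exceeding a prominence of 0.0005 —
roughly the smallest level separation that survives smoothing at
typical analytical noise. The local/non-local call
(`classifyLocal()`) is an explicit envelope rule: an individual is
non-local when any feature falls outside [min(μ−2σ), max(μ+2σ)] over
the cells within 50 km of the site. This operationalizes what is
usually a map-reading judgement; the output carries the rationale and
the offending features so the judgement stays inspectable.

## Season, elevation, relocations

`fitSeasonalAnchor()` fits mean + A·sin(2π(d−φ)/P) to the δ¹⁸O series
by Levenberg–Marquardt least squares, seeding the period from the
dominant discrete-Fourier component and restarting over a small period
grid (sinusoid fits have many local optima in P). One period is one
year of crown growth; peaks are summers. A fit whose amplitude is
below twice the residual SD is flagged degenerate — worn teeth of old
horses genuinely lose their cycles and must not be force-anchored.
Both the fitted amplitude and the raw range (`profileAmplitude()`)
are computed; summary statistics use the raw range.

The carbon chain (`enamelToElevation()`) inverts
δ¹³C_diet = a·elevation + b with a = −1.45·10⁻³ ‰/m (SE 3.07·10⁻⁴)
and b = −24.14 ‰ (SE 0.71): enamel is first shifted −2 ‰ for the
Suess effect (only archaeological samples — the calibration is
modern, and modern samples already share the industrial atmosphere),
then converted to diet with the −13.7 ‰ diet–enamel fractionation for
horses. Uncertainty is Monte Carlo over Gaussian draws of a and b
(n = 10 000 by default) because the quoted standard errors are far too
large for first-order propagation to be honest. Estimates below
1500 m are *flagged* implausible for a high-mountain study region,
never clipped: the profile's internal variation is the signal, the
absolute elevation only an indication.

Relocations are counted by exact penalized change-point segmentation
(`peltSegment()`, a PELT-style dynamic program on squared-error cost
with a 5-sample minimum segment). The default penalty is built for
kernel-smoothed enamel records: every true camp switch appears as a
monotone ramp spanning roughly the rolling window plus the maturation
window, so the penalty sits just above the gain of splitting such a
ramp (transition length × gap²/16, with the gap estimated from the
10–90% quantile range) and well below the gain of capturing a genuine
level alternation. A BIC-type noise floor (2σ̂²log n) guards the
high-noise limit. The per-year rate divides the boundary count by the
years of crown covered, taken from the seasonal anchor's period.

## The forward model

`annotateTrack()` samples the isoscape at each GPS fix (containing
cell, half-open convention; out-of-extent fixes excluded with a
count, long gaps flagged). `predictProfile()` turns the annotated
track into a time-weighted residence series — each fix holds until
the next, so irregular collar schedules do not overweight
burst-sampled places — and runs it through *the same* recording
kernel as the synthetic generator. That shared kernel is a package
invariant under test: if the forward model and the simulator ever
disagree on a common input, the suite fails.

## Radiocarbon chronology

`calibrate()` computes the calendar posterior of a conventional age on
a 1-year grid over the curve support, with variance σ² + σ_curve(θ)²
and trapezoidal normalization; it refuses dates whose posterior mass
touches the grid boundary. The curve reader understands the
comma-separated IntCal `.14c` dialect. `qcFilter()` applies the
collagen-preservation rule — atomic C/N in [3.1, 3.3] *or* extraction
yield ≥ 5% — and excludes indeterminate samples with a reason.

`phaseModel()` is the single-phase model: latent calendar dates
θᵢ are iid uniform on [β, α] *with* the 1/(α−β) interval normalization
per date, and a flat prior on (α, β) over the curve support. Sampling
is Metropolis-within-Gibbs — vectorized random-walk updates for θ
whose step shrinks with the phase width, exact inverse-CDF draws for α
and β (their full conditionals are truncated powers of the span), and
a joint translation move of the whole phase that keeps narrow phases
mobile. Four chains, 20% burn-in, and a split-R̂ gate at 1.1 on both
boundaries; non-convergence is an error, not a warning.

The span prior was the one genuinely open design choice, and we
settled it by calibration rather than convention: under the model's
own generative process (uniform dates in a known phase, noisy
measurement through the curve), the normalized uniform-phase model
covers the true start and end with its 95.4% HPD at the nominal rate
(measured 97–99% per boundary over 100 seeded replicates). Adding a
further Jeffreys-type 1/(α−β) factor collapses the span posterior
toward zero (median ~1.5 y for a true 50 y phase) and drops coverage
to ~60%; making the *net* density 1/(α−β) over-spreads it by an order
of magnitude. Both variants remain available through `spanPower`.
HPDs are reported at 95.4% (the 2σ radiocarbon convention) alongside
medians, and `calBPtoBCE()` converts with the 1950 datum and no year
zero (cal BP 2991 = 1042 cal BCE).

## What the synthetic generators emulate — and what they do not

`makeIsoscape()` produces a smooth regional background with connected
lithological patches of distinct ratio and a per-cell SD layer —
the structure that makes assignment informative. It does not emulate
drainage networks, aeolian mixing, or the long-tailed error structure
of a real covariate-driven prediction. `makeSeasonalSchedule()` +
`simulateEnvironment()` encode the camp-rotation regime of mountain
pastoralism (four to five moves per year between low winter and high
summer pastures; δ¹⁸O mean −12.8 ‰, amplitude 2.45 ‰ so the annual
range is 4.9 ‰); residence is instantaneous and exclusive — no grazing
radius around camps, no transit. `recordTooth()` maps crown distance
to time linearly (no growth-rate model exists to justify more) and
averages the environment over a rectangular maturation window; real
amelogenesis is a two-stage, spatially graded process that this
one-parameter kernel only approximates. Passing the recovery tests
therefore shows the *inference chain* is correct and well calibrated
on its stated model, not that real enamel meets that model.

Two simulation-scale choices deserve explicit statement. First, the
generator's default maturation window is 180 days (bulk drill
sampling integrates months of signal), but the laser-ablation recovery
simulations use 45 days: laser transects target the inner enamel
layer, which mineralizes early and limits attenuation — with a
180-day window over ~91-day residencies the rectangular kernel sits
on a null of its own transfer function and no method could see the
switches. Second, simulated Sr profiles carry 1000 points per crown,
the density of a real laser transect (~35 points per 2 mm), because
the window-35 smoother is itself calibrated to that density; at
drill-sample density the same window spans a whole season.
Problem sizes throughout the tests (500 training sites, 1000-point
profiles, 50–100 replicates, 6000–25 000 MCMC draws) were chosen as
the smallest at which the checked quantities stabilize.

## Numerical choices and degenerate inputs

* Window means in the recorder are exact integrals of the
  piecewise-linear interpolant (cumulative-integral closure), so
  recording is exactly linear in the input and closed-form tests are
  meaningful at 10⁻¹² rather than quadrature tolerance.
* Posterior surfaces are computed from log-likelihoods shifted by
  their maximum before exponentiation; an all-invalid box is an error.
* Ties in `topArea()` break by column-major cell index; an all-equal
  posterior yields the first cells in index order, by contract.
* Constant profiles: smoothing returns the constant with zero SD
  (the rolling statistics are computed on a shifted series to avoid
  catastrophic cancellation); segmentation returns zero boundaries;
  the seasonal fit flags degeneracy instead of anchoring.
* `correctInterferences()` flags points whose corrected ⁸⁶Sr beam is
  non-positive instead of producing nonsense ratios.
* Elevation inversion guards the Monte Carlo slope draws away from
  zero (the far tail of a Gaussian slope would otherwise flip sign).

## Known limitations

Assignment treats profile features independently — no joint multi-
feature or multi-isotope likelihood. CV is not spatially blocked.
The phase model has no reservoir corrections, ordering constraints or
multi-phase structure. The elevation calibration is regional; outside
mountain-steppe C₃/C₄ gradients the δ¹³C–elevation reading does not
transfer. Relocation counts are lower bounds: moves within an
isotopically homogeneous area, or residences shorter than the
effective recording resolution (about a month), leave no countable
signature.
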