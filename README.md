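# isoMobility

Multi-isotope reconstruction of seasonal livestock mobility from
sequentially sampled tooth enamel.

Hypsodont molars mineralize over several years without later
remodelling, so isotope values sampled along a crown are a time series
of an animal's early life: **⁸⁷Sr/⁸⁶Sr** fingerprints the geology it
grazed, **δ¹⁸O** cycles with the seasons and provides the clock, and
**δ¹³C** tracks the C₃/C₄ forage gradient that, in mountain steppe,
follows elevation. `isoMobility` turns such intra-tooth records into
mobility statements — where an animal came from, how often its herd
relocated, at what elevations it fed, and over what calendar span a
site's animals were deposited.

## What it implements

| Stage | Functions |
|---|---|
| LA-MC-ICP-MS reduction | `correctInterferences()`, `bracketNormalize()`, `rollingSmooth()` |
| Isoscape fitting | `extractCovariates()`, `filterCorrelated()`, `selectVariables()`, `fitIsoscape()`, `validatePoints()` |
| Geographic assignment | `profileFeatures()`, `posteriorSurface()`, `topArea()`, `nestedAssignment()`, `classifyLocal()` |
| Season & elevation | `fitSeasonalAnchor()`, `profileAmplitude()`, `enamelToElevation()`, `countRelocations()` |
| Radiocarbon chronology | `qcFilter()`, `readCalCurve()`, `calibrate()`, `phaseModel()`, `calBPtoBCE()` |
| Forward model | `annotateTrack()`, `predictProfile()`, `compareProfiles()` |
| Synthetic ground truth | `makeIsoscape()`, `makeSeasonalSchedule()`, `simulateEnvironment()`, `recordTooth()`, `makeRadiocarbonDataset()` |
| Orchestration | `validateConfig()`, `runPipeline()`, plus a thin CLI in `inst/scripts/isomobility` |

The geographic assignment is Bayesian on a continuous surface: for a
profile feature with smoothed mean *m* and rolling SD *s*, each cell
of an isoscape box contributes the likelihood
N(*m*; μᵢ, σᵢ² + *s*²), normalized to a posterior under a uniform
prior, from which the top 10% of the area is extracted. The isoscape
itself is a 3000-tree random forest with quantile-regression
prediction intervals supplying the per-cell σᵢ. Elevation inverts the
calibration δ¹³C_diet = −1.45·10⁻³·elev − 24.14 (after a −2 ‰ Suess
shift for archaeological enamel and the −13.7 ‰ diet–enamel
fractionation). Relocations are counted by exact penalized
change-point segmentation of the smoothed Sr series, and the
radiocarbon dates enter a single-phase Bayesian model with
start/end/span posteriors at 95.4% HPD. The methods vignette
(`vignettes/methods.Rmd`) derives each model and records the design
decisions.

## Worked example

A synthetic herd alternates four times a year between two camps in
strontium zones 0.002 apart; an M2 records ~2.5 years of that regime
at laser-transect density, and the package recovers the regime from
the tooth alone:

```r
library(isoMobility)

iso <- SrIsoscape(cbind(matrix(0.7110, 40, 20), matrix(0.7130, 40, 20)),
                  matrix(0.001, 40, 40), cellSize = 1000)
camps <- data.frame(x = c(10e3, 30e3), y = c(20e3, 20e3),
                    elevation = c(1900, 2500))
sch <- makeSeasonalSchedule(camps, nYears = 4, switchesPerYear = 4)
env <- simulateEnvironment(sch, iso)
tooth <- recordTooth(env, ToothTiming("M2"), maturationWindowDays = 45,
                     nSamples = 1000,
                     noiseSd = c(Sr = 5e-4, d18O = 0.3, d13C = 0.1), seed = 1)

sr <- rollingSmooth(tooth$Sr, 35)
(anchor <- fitSeasonalAnchor(tooth$d18O))
#> SeasonalAnchor: amplitude 2.39 permil, period 28.0 mm/yr, 2.50 yr covered

rel <- countRelocations(sr, anchor)
#> 10 boundaries -> 4.00 relocations per year   (truth: 4/year)

elev <- enamelToElevation(values(tooth$d13C), isArchaeological = FALSE, seed = 1)
#> mean 2198 m, range 1006 m                    (camps: 1900 and 2500 m)

classifyLocal(profileFeatures(sr), iso, siteXY = c(20e3, 20e3))$status
#> "local"
```

The δ¹⁸O sinusoid dates the crown (28 mm per year, 2.5 years
recorded), the segmentation finds the ten camp switches the schedule
actually contains, the δ¹³C inversion brackets the two camp
elevations, and every profile feature sits inside the local isoscape
envelope, so the animal is called local.

Radiocarbon dates drawn from a known 50-year phase are summarized the
same way the chronology of a real site would be:

```r
curve <- syntheticCalCurve(c(2400, 3600), curveSd = 10,
                           wiggleAmplitude = 20, wigglePeriod = 150)
dates <- makeRadiocarbonDataset(3000, 2950, 8, curve, 25, seed = 1)
phaseSummary(phaseModel(dates, curve, seed = 1))
#>   parameter     median    hpd_lower hpd_upper level
#> 1     start 3014.67789 2981.7382462 3071.1065 0.954
#> 2       end 2955.07029 2882.0079132 2992.7662 0.954
#> 3      span   62.52211    0.2086425  168.5562 0.954
```

Both true boundaries (3000 and 2950 cal BP) fall inside their 95.4%
HPD intervals.

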