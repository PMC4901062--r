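# swiatlas

Subject-specific visualization and demarcation of thalamic nuclei from
high-field MR data, for preclinical deep brain stimulation (DBS) work and
anyone who needs per-subject nucleus boundaries rather than a one-size
atlas overlay.

Thalamic nuclei are nearly invisible on conventional MR contrast, yet most
of them are stereotactic targets. The package implements a complete
toolchain around two ideas:

1. **Susceptibility weighting.** Iron-rich nuclei shift the gradient-echo
   phase negative. A phase mask

   *M*(v) = 1 if φ(v) ≥ 0, else 1 + φ(v)/π,

   raised to a power *m* (default 4) and multiplied into the magnitude
   image renders those nuclei hypointense: SWI = mag · *M*^m.

2. **Fold-free moving-least-squares (MLS) atlas warping.** Matched
   landmarks (p_i, q_i) on an atlas plate and the corresponding coronal
   slice drive a per-pixel transform f(x) = xM + T minimizing
   Σ_i w_i |f(p_i) − q_i|², with w_i = 1/|p_i − v|^(2α) and α = 2.
   Closed forms exist for affine, similarity and rigid modes. Large warps
   are decomposed into partial deformations, each accepted only if its
   Jacobian determinant keeps one sign on the grid, so the warp never
   folds the image back on itself.

Around these sit: AC-PC reslicing, Talairach-style proportional plate/slice
matching, global rigid + local affine landmark registration, lofting of
warped contours into 3D label volumes, anterior-commissure intensity
normalization, per-nucleus statistics, age correlation, a two-group
t-test and Cook's-distance outlier screening. Seeded phantom generators
emulate every input, so the whole pipeline runs and is tested without any
scanner data.

## Worked example

Age correlation and influence screening on the bundled seven-subject
reference cohort (ages 4-22 y, seven thalamic nuclei with AC-normalized
SWI intensity summaries):

```r
library(swiatlas)
co <- referenceCohort()
ageCorrelationAll(co)
#>    nucleus      r df       p n
#> 1 Pulvinar -0.730  5 0.06246 7
#> 2      MGN -0.909  5 0.00459 7
#> 3     VPLc -0.785  5 0.03634 7
#> 4     VPLo -0.369  5 0.41490 7
#> 5       MD -0.568  5 0.18357 7
#> 6      VLo -0.294  5 0.52248 7
#> 7       VA -0.343  5 0.45149 7
```

The posterior nuclei (MGN, VPLc; pulvinar borderline) darken
significantly with age — consistent with age-dependent iron accumulation —
while the anterior/ventral nuclei and MD do not. Influence screening at
the 3×-mean Cook's-distance threshold:

```r
subset(cooksOutliersCohort(co), flag)
#>    nucleus subject distance flag
#> 16    VPLc       2    0.786 TRUE
#> 23    VPLo       2    0.584 TRUE
#> 30      MD       2    0.778 TRUE
#> 37     VLo       2    0.970 TRUE
#> 44      VA       2    0.893 TRUE
```

Subject 2 is influential in every nucleus except pulvinar and MGN.

SWI reconstruction on a seeded phantom with a π/2 phase-shifted
"pulvinar-like" region:

```r
ph  <- makePhantom(phantomSpec(), seed = 1)
swi <- combineSWI(ph$magnitude, ph$phase, m = 4)
regionStats(swi, ph$labels)
#>    nucleus   mean sd voxels
#> 1  ventral 100.00  0   1416
#> 2 pulvinar   6.25  0   1072
#> 3      MGN  19.75  0    280
```

The pulvinar-like region is attenuated by exactly 0.5^4 = 0.0625, the
closed-form prediction for φ = −π/2 at m = 4.

Warping an atlas plate onto a synthetic subject:

```r
plate <- AtlasPlate("P1", 8, list(VPLo = ..., VPLc = ...))
pair  <- makeDeformedPair(plate, list(type = "sinusoid",
                                      amplitude = c(1.5, 1.2),
                                      period = c(40, 36)))
ws   <- partialWarpSequence(pair$cps, c(64, 64), MLSConfig())
warped <- warpContours(plate, ws)        # contours on the subject slice
```

A thin command-line wrapper lives in `inst/cli/swiatlas-cli.R`
(`swi`, `phantom`, `age-corr`, `outliers` subcommands).

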