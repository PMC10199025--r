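# lvmap

Spatiotemporal mapping and bias correction of time-varying left-ventricular
(LV) geometries.

Different cardiac imaging protocols measure the same ventricle differently:
3D echocardiography (3DE) systematically underestimates LV volumes relative
to cardiac magnetic resonance (CMR), the disagreement varies regionally
over the wall, and the two acquisitions sample the cardiac cycle at
different rates and heart rates. `lvmap` corrects such inter-protocol bias
at the level of the geometry itself, so that every downstream index
(volumes, mass, ejection fraction, strain, filling rates) is corrected at
once. It is aimed at groups pooling chamber quantification across
modalities, analysis tools or institutional protocols.

## Method

Per subject, the two protocols' cavity-volume traces `T` (n = 30 uniform
samples) and `S` (m = 60) are normalised to [0, 1] and aligned by dynamic
time warping with a time-expansion penalty `p` (the maximum per-phase
difference between the normalised traces):

    d(i, j)     = (t_i - s_j)^2
    gamma(i, j) = d(i, j) + min[ gamma(i-1, j), gamma(i-1, j-1), gamma(i, j-1) + p ]

The optimal monotonic, continuous path with fixed endpoints yields warped
fractional indices `j'_i` (the mean of the secondary indices paired with
template index `i`), at which the target geometry is evaluated by linear
interpolation — a one-to-one frame correspondence.

Across subjects, the aligned geometries are flattened to rows of
290 points x 3 coordinates x 30 frames = 26,100 columns, mean-centred and
z-normalised, and related by PLS regression (NIPALS, PLS2):

    X = T P',   Y = U Q',   U = T beta,   Y_hat = T beta Q' = X P beta Q'

with the number of latent components chosen by 5-fold cross-validation.
Mapping performance is estimated by leave-one-out cross-validation and
reported as index agreement (bias, 95% limits of agreement, ICC(A,1),
paired t-tests), global and AHA 17-segment geometry RMSE, and cumulative
DTW distances between volume/strain traces.

Because paired clinical datasets of this kind are not public, the package
includes a synthetic paired-population generator whose inter-protocol bias
(global volume scale, reduced apparent contraction, apical foreshortening,
a basal-anterolateral offset field, a monotone temporal warp, heart-rate
change, point noise) is known exactly and recoverable — every pipeline
stage is validated against that ground truth. See the methods vignette
(`vignettes/spatiotemporal-mapping.Rmd`) for the full design.

## Worked example

```r
library(lvmap)

pop <- generatePopulation(nSubjects = 20, seed = 7)   # paired 3DE-like / CMR-like
s   <- pop$subjects[[1]]

computeIndices(s$target)
#>        EDV      ESV      LVM       EF       GLS       PER    PFR_E   PFR_A       PSR
#> 1 165.6047 66.28369 141.5411 59.97475 -18.95256 -530.9077 511.9502 146.746 -1.098123
computeIndices(s$source)
#>        EDV      ESV      LVM       EF       GLS       PER    PFR_E  PFR_A       PSR
#> 1 148.1009 80.45158 131.5384 45.67787 -17.03872 -398.3811 320.1462 125.14 -1.026768

ap <- alignPair(s$source, s$target)   # per-subject DTW alignment
ap
#> AlignedPair 'S2099865043': 30 aligned frames, p = 0.0911 (equation), cost 2.772,
#> discrepancy 0.04122 -> 0.003327

ev <- evaluateMapping(pop, kMax = 8)  # align, fit PLS, leave-one-out evaluate
ev
#> lv_mapping_eval: 20 subjects, 8 PLS components
#>   global RMSE: 1.86 +/- 0.16 -> 0.62 +/- 0.26 mm
#>   EDV   bias  -14.73 ->   -0.37   ICC 0.893 -> 0.992
#>   ESV   bias   11.24 ->    1.39   ICC 0.861 -> 0.943
#>   LVM   bias   -9.11 ->   -0.15   ICC 0.986 -> 0.997
#>   EF    bias  -13.88 ->   -0.85   ICC 0.452 -> 0.849
#>   ...
```

The first block shows the injected protocol bias on one subject (the
3DE-like source underestimates EDV by ~18 ml and EF by ~14 points). The
alignment report shows the warping penalty and the drop in trace
discrepancy after warping. The evaluation summary shows the leave-one-out
result: mean index biases shrink by roughly an order of magnitude, ICC
rises for every index, and the mean surface RMSE against the target
geometry drops about three-fold.

A command-line interface wraps the same pipeline
(`inst/cli/lvmap simulate | align | indices | fit | apply | evaluate`);
sequences are stored as a CSV point table with a JSON sidecar header.

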