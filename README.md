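# ivimsim

Simulation and estimation of intravoxel incoherent motion (IVIM)
parameters in whole-brain diffusion MRI.

## The problem

IVIM imaging measures tissue perfusion without contrast agents by
exploiting the bi-exponential decay of the diffusion-weighted MRI
signal,

    S(b) = S0 · ( f · exp(−D*·b) + (1 − f) · exp(−D·b) ),

where `S0` is the unweighted signal, `f` the perfusion fraction, `D*`
the pseudo-diffusion coefficient of capillary blood (mm²/s) and `D` the
tissue diffusion coefficient (mm²/s). At whole-brain resolution
(1 × 1 × 2 mm voxels) a quick clinical protocol reaches a b0
signal-to-noise ratio near 20, and the reliability of the four
estimates at that SNR is the question this package answers, for users
designing or evaluating IVIM protocols: physicists, methods researchers
and anyone deciding whether single-voxel IVIM maps or ROI-averaged
estimates are trustworthy at their scanner's SNR.

The package provides:

* the forward model and the 35-measurement acquisition scheme
  (5 × b0 + 10 b-values in {10…1200} s/mm² × 3 directions);
* Rician noise simulation at controlled SNR (`sigma = S0 / SNR` per
  quadrature channel) and voxel-cluster averaging (8/27/64);
* three estimators: segmented exhaustive **grid search** (two-stage
  least-squares MLE, split at b = 250 s/mm²), segmented bounded
  **curve fit**, and **one-step** four-parameter bounded curve fit;
* a Monte-Carlo driver sweeping SNR 15–50 that tabulates relative RMSE
  (%) per parameter × method × averaging factor, with Monte-Carlo
  standard errors;
* volume tools: per-voxel SNR maps from repeated b0 scans, ROI-averaged
  normalized signals, voxelwise parameter maps, estimate-range
  classification; NIfTI-1 + FSL bval/bvec I/O;
* a deterministic GM/WM/CSF digital phantom for end-to-end testing, and
  a command-line front end (`inst/cli/ivim.R`) with `simulate`, `fit`,
  `snr-map`, `phantom`, `classify` and `report` subcommands.

## Worked example

Fit one noisy realization, then run a scaled-down accuracy study:

```r
library(ivimsim)

truth <- IVIMParams(s0 = 1, f = 0.12, dstar = 0.01, d = 0.001)
noisy <- addRicianNoise(cleanSignalSet(truth, defaultScheme(), 1),
                        noiseSpec(20, seed = 7))
fitGridSegmented(signalValues(noisy)[1, ], defaultScheme())
#> FitResult [grid_search]: S0 = 1.005, f = 0.1045, D* = 0.003981, D = 0.001025
#>   SSE = 0.08664
```

A single voxel at SNR 20 gets `S0` and `D` about right, while `f` and
especially `D*` scatter badly — quantified by the Monte-Carlo study:

```r
cfg <- simulationConfig(snrLevels = 20, nRealizations = 3456L,
                        averagingFactors = c(1L, 8L, 27L, 64L),
                        methods = "grid_search", seed = 1L)
tab <- runStudy(cfg)
exportRMSETable(tab, snr = 20)
#>         averaging parameter grid_search
#> 1    single voxel        S0        2.99
#> 2    single voxel         f       69.95
#> 3    single voxel        D*      254.15
#> 4    single voxel         D       14.28
#> 5   8 (2 x 2 x 2)        S0        0.64
#> 6   8 (2 x 2 x 2)         f       27.62
#> 7   8 (2 x 2 x 2)        D*       83.39
#> 8   8 (2 x 2 x 2)         D        5.16
#> 9  27 (3 x 3 x 3)        S0        0.39
#> 10 27 (3 x 3 x 3)         f       15.92
#> 11 27 (3 x 3 x 3)        D*       26.82
#> 12 27 (3 x 3 x 3)         D        3.18
#> 13 64 (4 x 4 x 4)        S0        0.28
#> 14 64 (4 x 4 x 4)         f       10.57
#> 15 64 (4 x 4 x 4)        D*       16.14
#> 16 64 (4 x 4 x 4)         D        2.20
```

Each cell is the relative RMSE in percent of the named parameter at
SNR 20; rows group by voxel-averaging factor. Reading it: single-voxel
`S0` is excellent (~3%), `D` usable (~14%), `f` marginal (~70%) and
`D*` unusable (>200%, dominated by estimates pinned at the search-range
boundaries — see the vignette on why that number is a joint property of
estimator and search range). Averaging 27 neighbouring voxels brings
`f` to ~16% and `D*` to ~27%, which is the practical argument for
ROI-based IVIM at this resolution. `plotRMSEvsSNR(tab)` draws the
corresponding per-parameter curves across an SNR sweep.

Volume-level use follows the same functions on NIfTI data:

```r
ph <- makePhantom(phantomSpec(), outDir = "phantom/")
vol <- readDWI("phantom/dwi.nii.gz", "phantom/dwi.bval", "phantom/dwi.bvec")
snrMap(vol)                      # per-voxel SNR from the five b0 scans
maps <- fitVolume(vol, "grid_search")
classifyEstimates(maps$f, maps$dstar, vol@mask)
```

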