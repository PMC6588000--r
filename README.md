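# radialT1

Model-based reconstruction of quantitative T1 and proton-density (M0) maps
directly from undersampled golden-angle radial stack-of-stars MRI k-space
data.

## The problem and who this is for

Quantitative T1 mapping conventionally reconstructs one image per
acquisition parameter (flip angle, or inversion time) and then fits a
signal model voxel by voxel.  With heavily undersampled radial
acquisitions the intermediate images are artifact-ridden and the fit
degrades.  This package — aimed at MRI reconstruction researchers and
quantitative-imaging method developers — skips the intermediate images and
fits the parameter maps directly to the measured multi-coil k-space
samples:

    A : u = (M0, T1)  ↦  { F_p [ b_c · S_p(M0, T1) ] }_{p,c}

    minimize_u  ½ ‖A(u) − d‖₂² + λ TGV²_Frob(u)

Here `S_p` is the analytic signal model of parameter encoding `p` —
variable flip angle (VFA, spoiled gradient echo:
`S = M0 sin α (1−E1)/(1−E1 cos α)`, `E1 = exp(−TR/T1)`) or
inversion-recovery Look-Locker (IRLL, transient readout train after an
inversion pulse) — `b_c` the coil sensitivities and `F_p` the non-uniform
Fourier transform along encoding `p`'s radial spokes (Cartesian along kz).
The regularizer is second-order total generalized variation with a
Frobenius norm coupling both maps, so shared edges are preserved jointly
(TV and slice-wise Daubechies-4 L1-wavelet regularization are available
alternatives, each with joint or separate coupling and 3D or 2D
derivative support).

The nonconvex problem is solved by an iteratively regularized Gauss-Newton
(IRGN) scheme: each outer step linearizes `A` and solves a convex
subproblem with a primal-dual algorithm with line search; the
regularization weight λ decays geometrically (factor 0.7, clamped at a
trained floor) while the Gauss-Newton damping weakens (γ doubling up to
100).  A synthetic-data module (digital brain phantom, Biot-Savart coil
sensitivities, continued golden-angle sampling, complex Gaussian noise)
generates study data, and evaluation utilities compute MRAE, SSIM, ROI
statistics and joint histograms.  See the methods vignette
(`vignettes/model-based-t1-mapping.Rmd`) for the full story.

## Worked example

```r
library(radialT1)

# a 32x32x4 digital brain phantom, 21 continued golden-angle spokes per
# flip angle, 10 flip angles 1-19 deg, TR 5.38 ms, 5 coils, 30 dB k-space SNR
ds <- simulate_dataset(shape = c(32, 32, 4), spokes = 21, n_coils = 5,
                       snr_db = 30, seed = 3)

cfg <- irgn_config(gn_steps = 5, pd_iters = c(50, 100, 150))
fit <- irgn_reconstruct(ds$data, ds$model, ds$coils, ds$traj, cfg,
                        labels = ds$truth$labels)
print(fit)
#> Model-based VFA T1 fit (TGV, joint coupling, 3D regularization)
#>   grid 32 x 32 x 4, 5 coils, 10 encodings, 5 GN steps (completed)
#>   T1 over non-zero voxels: median 906 ms, IQR 705-1346 ms
#>   final lambda = 0.0024, gamma = 100, primal energy = 1981.34

mrae(fit$T1, Re(ds$truth$T1))       # masked T1 error, percent
#> [1] 6.395923
roi_stats(fit$T1, ds$truth$labels)  # per-tissue mean/SD (ms)
#>   label      mean        sd    n
#> 1     1  919.4809 125.06159  612
#> 2     2 1402.6168  69.09021 1000
#> 3     3 3448.0516 378.27084   72
#> 4     4 1568.4530 281.45858   28
```

The fitted object supports `coef()` (the maps), `predict()` (model
k-space), `residuals()`, `summary()` (GN diagnostics + ROI table) and
`plot()` (T1/M0 slices).  `write_maps()` exports NIfTI volumes;
`write_dataset()`/`read_dataset()` round-trip a self-contained dataset
container.

A command-line front end (`inst/cli/radialt1.R`) chains the same steps:

```sh
Rscript inst/cli/radialt1.R simulate --out data.rds --shape 32,32,4 --spokes 21 --seed 1
Rscript inst/cli/radialt1.R recon    --data data.rds --out fit --reg tgv --coupling joint --reg-dim 3
Rscript inst/cli/radialt1.R evaluate --data data.rds --fit fit.rds --out report.json
```

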