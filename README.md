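# mitoradial

Quantifying **where mitochondria sit inside a cell**, and **why**.

In beta-cell-like (insulin-secreting) cells, mitochondria redistribute
radially with glucose and cAMP/PKA signaling: stimulation shifts
mitochondrial mass toward the cell periphery. `mitoradial` is an R package
for scientists studying this kind of organelle positioning. It provides:

* **Segmentation** of mitochondrial voxels in single-channel fluorescence
  z-stacks: per-slice Gaussian smoothing (σ = 2 px), Laplacian sharpening,
  fixed-threshold binarization (counts > 750), 3D 26-connected component
  labeling, and size filtering (components ≤ 125 or ≥ 100,000 voxels
  removed).
* **Radial analysis**: per-pixel Euclidean distances to the annotated
  nucleus center (physical µm, anisotropic voxels), normalized per cell by
  the maximum mitochondrial-pixel distance so every cell maps onto [0, 1];
  pixel-weighted pooling by condition; the peripheral subset (30% most
  distant pixels); two-sample Kolmogorov-Smirnov comparisons (exact
  permutation p when `n1·n2 ≤ 1e4`, asymptotic otherwise).
* **A stochastic transport model**: point mitochondria in a unit disk
  switch between a microtubule-bound state — purely radial motion at the
  drift velocity

  `v_drift = v₊ · PKA/(1+PKA) − v₋/(1+PKA)`

  (kinesin-driven anterograde vs dynein-driven retrograde transport,
  partitioned by a saturating PKA signal) — and a free state (isotropic
  diffusion, reflecting boundary). Time is measured in units of the bound
  lifetime (`k_unbind = 1`). Steady-state radial distributions, mean-radius
  sweeps over (PKA, k_bind), and grid-search least-squares fits to observed
  histograms.
* **A phantom generator**: synthetic z-stacks with capsule-shaped
  mitochondria, a dark nucleus, configurable radial placement laws
  (`uniform-disk`: CDF r²; `peripheral-shifted(s)`: CDF r^(2+s)), noise
  models, and exact voxel-level ground truth — the whole pipeline is
  testable without a microscope.

See `vignettes/mitoradial-methods.Rmd` for the model, parameter defaults
(including how the dimensionless diffusion constant 0.0008 is derived), and
every numerical design choice.

## Worked example

Two synthetic conditions — one with peripherally shifted mitochondria, one
uniform over the cell area — run through the full pipeline:

```r
library(mitoradial)

spec_uniform <- phantom_spec(stack_shape = c(9, 192, 192), cell_radius = 4,
                             nucleus_radius = 0.4, n_mito = 12,
                             mito_length_range = c(0.5, 1.2), mito_radius = 0.22)
spec_shifted <- spec_uniform
spec_shifted$radial_density <- radial_density("peripheral-shifted", strength = 1.5)

cfg <- run_config(
  conditions = list(high = list(spec = spec_shifted, n_cells = 8),
                    low  = list(spec = spec_uniform, n_cells = 8)),
  seg = segmentation_config(gaussian_sigma = 2, threshold = 750),
  fraction = 0.30, seed = 42)
run_pipeline(cfg)
#> pipeline_report
#>   high: 8 cells (0 excluded), 33346 pixels, mean norm. distance 0.6624
#>   low: 8 cells (0 excluded), 33304 pixels, mean norm. distance 0.5972
#>   high vs low (peripheral): D = 0.0889, p = 1.01e-34
```

Each condition's ~33k segmented mitochondrial pixels pool into a normalized
radial distribution; the shifted condition's mean normalized distance is
larger (0.66 vs 0.60), and the KS test on the peripheral 30% subsets
separates the conditions (D = 0.089). (The p-value illustrates the
pixel-pooling caveat above: it counts pixels, not mitochondria, so it
overstates the evidence — effect sizes are the robust readout.)

The transport model at the reference parameter set (`k_bind = 0.025`,
`PKA = 0.7`, `v₊ = v₋ = 0.4`, 5000 walkers) produces an interior, mid-cell
mode — inward bound-state drift (`v_drift < 0`) balancing the outward bias
of 2D diffusion in a disk:

```r
sim <- run_simulation(sim_params(k_bind = 0.025, pka_signal = 0.7,
                                 v_plus = 0.4, v_minus = 0.4,
                                 dt = 0.02, n_steps = 50000, seed = 42))
sim
#> sim_result: 5000 walkers, 50000 steps, mean radius 0.5355
classify_peak_location(radial_histogram(sim$r, n_bins = 20))
#> [1] "mid"
drift_velocity(0.7, 0.4, 0.4)
#> [1] -0.07058824
```

## Command line

```sh
exec/mitoradial simulate --pka 0.7 --kbind 0.025 --n 5000 --steps 50000 \
    --seed 42 --out sim            # radii CSV + trajectory CSV + params JSON
exec/mitoradial sweep --pka 0,0.7,1.5,3 --kbind 0,0.025,0.1 --out sweep.csv
exec/mitoradial segment --stack cell.tif --threshold 750 --out cell
exec/mitoradial run --config run.yaml   # full pipeline from a YAML config
```

The YAML layout for `run` mirrors `run_config()`; see
`?read_run_config` and `tests/testthat/test-pipeline.R` for a complete
document.

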