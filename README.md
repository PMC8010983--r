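# nanomem

Trajectory analysis for molecular-dynamics studies of self-assembling
**drug amphiphiles** (DAs — conjugates of a hydrophobic drug such as
camptothecin, a linker, and a short peptide) interacting with a **POPC
model membrane**. The package is aimed at simulators who have long
trajectories of DA/membrane systems and need the standard battery of
analyses behind such studies, each one testable against synthetic inputs
with known ground truth.

What it computes:

- **Nanoclusters** — connected components of the molecular contact graph
  (any heavy-atom pair within r_cut = 4.5 Å, minimum image), with
  number-weighted mean sizes, quartiles, extrema and box-plot outliers,
  and normalized sizes in (0, 1].
- **Cluster shape** — principal gyration radii from the inertia tensor
  (I = mR²) and the sphericity index κ = R_min/R_max (1 for a sphere, →0
  for a rod), plus the κ-versus-size OLS regression with 95% CI.
- **2D free-energy landscapes** — ΔG = −RT ln(P/P_max) over (normalized
  size, d_z), where d_z is the closest-atom distance of a cluster from the
  membrane centre of mass.
- **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 3 Å, D–H–A
  angle ≥ 120°), per-frame counts with a trailing 100-frame running
  average, and residue-pair occupancy / longest-episode lifetimes.
- **Membrane geometry** — leaflet assignment, gridded mid-surface,
  thickness profiles, triangulated surface area, Monge-gauge mean
  curvature, and the Helfrich bending energy F_bend = (k_c/2)∫(2H)² dA.
- **Umbrella sampling / WHAM** — window bookkeeping (e.g. 38 windows
  70.5→33.5 Å at 1 Å), harmonic biases w = (k/2)(ξ−q)², and a
  self-consistent WHAM solver yielding anchored PMF profiles.
- **Electrostatic-potential maps** — Gaussian-smeared charges, spectral
  (FFT) periodic Poisson solve, slab-averaged 2D slices in volts.
- **Synthetic data** — generators for bilayers (flat/bent, with quadrature
  ground truth), planted clusters, biased umbrella windows from a known
  PMF, scripted hydrogen-bond trajectories, and a composite DA/membrane
  system; every generator attaches its ground truth.

Inputs are PDB (topology + frame, CRYST1 box), extended-XYZ or DCD
multi-frame coordinates, and a sidecar CSV carrying per-atom roles,
charges and donor/acceptor annotation (see `?read_sidecar`).

## Worked example

```r
library(nanomem)

## composite synthetic system: a 288-lipid bilayer + three DA clusters
## hovering at planted closest-approach distances of 24, 32, 40 Å
traj <- make_da_membrane_composite(seed = 42, n_frames = 5)

find_clusters(traj$frames[[1]], traj$topology)
#> ClusterSet (frame 0): 25 molecules in 3 clusters, r_cutoff 4.50 A
#> sizes: 5 8 12

round(sort(unique(round(landscape_samples(traj)$dz, 1))), 1)
#> [1] 23.9 24.0 32.0 32.1 39.9 40.0       # planted 24 / 32 / 40 recovered

hf <- height_field(traj$frames[[1]], traj$topology)
hf
#> HeightField: 12 x 12 nodes (8.0 x 8.0 A spacing), 100% occupied
#>   thickness 38.01 +/- 0.36 A            # planted 38 Å bilayer
surface_area(hf)                          # ≈ 9230 Å² (box is 96 × 96 Å)

## umbrella sampling: recover a planted 3 kcal/mol double well from
## 38 windows (70.5→33.5 Å, k = 20 kcal mol⁻¹ Å⁻²)
dw <- function(x) 3 * (((x - 52) / 12)^2 - 1)^2
ds <- sample_biased_windows(dw, generate_windows(70.5, 33.5, 1),
                            k = 20, n_per_window = 5000, seed = 42)
res <- wham_solve(ds)
res
#> WhamResult: 190 bins, 116 iterations (residual 5.13e-08, converged)
#>   PMF range: [0, 6.159] kcal/mol
pmf_rms_error(res, dw, xi_range = c(33.5, 70.5))
#> [1] 0.239                               # kcal/mol vs the planted PMF
```

The cluster sizes, d_z values and membrane thickness are exactly the
planted ground truth; the WHAM error of ~0.24 kcal mol⁻¹ reflects the
small overlap of adjacent windows at k = 20 with 1 Å spacing (see the
methods vignette), and shrinks as samples per window grow.

`run_pipeline(analysis_config(seed = 1))` chains
cluster → shape → pmf2d → hbonds → membrane (plus optional wham/epmap)
stages and writes per-stage CSVs plus one JSON report; a thin command-line
front end over the same functions lives at `inst/scripts/mdda.R`.

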