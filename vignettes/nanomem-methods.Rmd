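---
title: "Methods: analysing drug-amphiphile / membrane simulations with nanomem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing drug-amphiphile / membrane simulations with nanomem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomem)
```

nanomem implements the analysis layer used to characterise long-timescale
simulations of self-assembling drug amphiphiles (DAs) — conjugates of a
hydrophobic drug such as camptothecin, a linker, and a short peptide —
interacting with a phosphatidylcholine (POPC) model membrane. The package
takes molecular trajectories plus per-atom metadata and produces nanocluster
statistics, cluster-shape measures, two-dimensional free-energy landscapes,
hydrogen-bond occupancies, membrane deformation metrics, umbrella-sampling
free-energy profiles, and electrostatic-potential maps. Every analysis is
validated against synthetic trajectories with known ground truth, generated
by the package itself.

Units are fixed package-wide: angstrom, nanosecond, atomic mass unit,
kcal mol⁻¹, elementary charge, and volts for electrostatic potentials. The
gas constant is R = 1.987204259×10⁻³ kcal mol⁻¹ K⁻¹ and the default
temperature is 310 K (body temperature, the thermostat setting of the study
systems), so k\_BT ≈ 0.616 kcal mol⁻¹. Boxes are orthorhombic; triclinic
cells are rejected explicitly. Atom indices are 1-based, the R convention.

## Role tags instead of chemistry

Analyses never parse residue chemistry. A sidecar table assigns each atom a
role (`drug`, `peptide`, `linker`, `lipid_head`, `lipid_tail`, `solvent`,
`ion`), a partial charge, and hydrogen-bond donor/acceptor flags with an
explicit polar-hydrogen-to-donor map. This keeps the package agnostic to
the MD engine and force field that produced the trajectory. Centre-of-mass
calculations use coordinates as given, without periodic unwrapping: the
synthetic generators emit whole molecules unwrapped, and for real input the
caller is responsible for providing unwrapped molecules where a COM matters.

## Nanocluster detection

Molecules aggregate into nanoclusters defined as connected components of a
contact graph: two molecules are linked when any pair of selected atoms
lies within r\_cut = 4.5 Å under the minimum-image convention. The distance
test is inclusive (d ≤ 4.5 Å), a measure-zero choice fixed for determinism.
Contacts are computed over drug-role heavy atoms by default (hydrogens
excluded, configurable), using a periodic cell list with cells at least one
cutoff wide; a quadratic all-pairs oracle (`contact_graph_oracle`,
`find_clusters_oracle`) is kept in the package and the two paths are
required to agree exactly in the tests.

Per-frame statistics report the number-weighted mean cluster size together
with quartiles, extrema and box-plot outliers (1.5 × IQR). The alternative
mass-weighted mean — the expected size of the cluster containing a randomly
chosen molecule — is exposed as an option; the number-weighted mean is the
documented default, not a claim about any particular prior work. Normalized
size is the cluster's molecule count divided by the total number of
selected molecules, a fraction in (0, 1]; a "percolated" state has
normalized size 1. Clusters are not tracked across frames.

## Cluster shape and sphericity

For each cluster the inertia tensor about its centre of mass,
I = Σᵢ mᵢ (|rᵢ|²𝟙 − rᵢrᵢᵀ), is diagonalised; with principal moments
I₁ ≤ I₂ ≤ I₃ and total mass m, the principal gyration radii follow the
I = mR² convention, R\_k = √(I\_k/m), and the sphericity index is
κ = R\_min / R\_max. κ equals 1 for any spherically symmetric mass
distribution and approaches 0 for a rod. Eigenvalue ties are broken by a
fixed ascending sort; κ uses strict min/max so the order is irrelevant. A
cluster whose smallest moment vanishes (collinear atoms) is reported as
κ = 0 with a degeneracy flag, and clusters below 4 atoms carry a
small-cluster flag but are not excluded — no exclusion rule is assumed.
The shape-versus-size trend is summarised by ordinary least squares of κ on
normalized size with t-based 95% confidence intervals (`sphericity_vs_size`);
a negative slope indicates aggregates that elongate as they grow, a
positive slope aggregates that round up.

Calibration uses closed forms: a uniform solid ellipsoid with semi-axes
(a, b, c) has principal moments m(b²+c²)/5 etc., so a 2:1:1 ellipsoid has
κ = √0.4 ≈ 0.632. The generator fills ellipsoids with a cubic lattice of
points (guaranteeing 4.5 Å connectivity); the lattice discretisation biases
κ by roughly (h/b)²/6 for spacing h and smallest semi-axis b, so shape
fixtures use h no larger than about b/10 to stay within 1% of the closed
form.

## Two-dimensional free-energy landscapes

The joint distribution of (normalized cluster size, d\_z) is converted to a
free-energy surface by Boltzmann inversion, ΔG = −RT ln(P/P\_max), so the
most probable bin sits at exactly 0 and every occupied bin is non-negative.
d\_z is the closest approach of a cluster to the membrane: the minimum over
cluster atoms of |z − z\_COM(membrane)|, with z the membrane normal. Empty
bins are undefined (NA), never +∞, and are excluded from minima; plots cap
the colour scale at a configurable ΔG\_max. The default grid is 50 × 50
over (0, 1] × [0, d\_max]; no particular bin width is canonical, and ΔG
differences between well-populated modes are insensitive to it (the tests
check a planted two-mode mixture against −RT ln(w₂/w₁)). Samples are
accumulated per cluster per frame — every cluster present in a frame
contributes one point — over a caller-chosen frame window.

## Hydrogen bonds

A donor–H···acceptor triplet counts as bonded when the donor-heavy-atom to
acceptor distance (minimum image) is ≤ 3.0 Å and the D–H–A angle is
≥ 120°, with 180° linear. The distance is deliberately donor-to-acceptor,
not hydrogen-to-acceptor, and the angle convention (≥, with 180° ideal) is
the chemically sensible reading of a 120° cutoff. Only bonds crossing the
two analysis groups are reported. Per-frame counts are smoothed with a
trailing 100-frame running average (shorter at the start of the series,
where only the available history is averaged). Residue-pair "lifetimes"
are reported two ways, since either reading is defensible: total occupancy
(fraction of frames with at least one atom-level bond between the two
residues — invariant to frame order) and the longest contiguous bonded
episode (order-sensitive). No kinetic, autocorrelation-based lifetime
constants are computed.

## Membrane geometry

Head-group atoms are split into leaflets in two passes: a global split
about the mid-point of the head z-range, then refinement against the local
mid-surface on an (x, y) grid. Nodes where a leaflet is missing, or where
the apparent separation falls below 5 Å (no credible bilayer), are flagged
uncovered — a single-leaflet sheet flags everything. The height field bins
head atoms on a grid (default 8 Å nodes, comparable to the area per lipid),
averages leaflet heights per node, fills isolated holes by linear
interpolation of periodic neighbours, and leaves larger holes unoccupied.

Thickness is the vertical (z) distance between leaflet head planes — not
the normal distance — which matches a density-profile reading of head-group
positions and is well defined on grids; profiles along x or y average over
the transverse direction. Mid-surface area is the sum of triangulated patch
areas (each cell split into two triangles, periodic wrap), exactly Lx·Ly
for a flat sheet. Mean curvature uses the Monge-gauge expression
H = [(1+z\_x²)z\_yy − 2z\_xz\_yz\_xy + (1+z\_y²)z\_xx] / [2(1+z\_x²+z\_y²)^{3/2}]
with periodic central differences — fourth-order stencils where the grid
allows (≥ 5 nodes per direction), because second-order differences at the
default 8 Å spacing leave a ~2% bias in the bending energy of smooth test
surfaces while fourth-order brings it to ~0.1%. Overhangs (surfaces folding
past vertical) are outside the Monge description and out of scope.

The Helfrich bending energy is F\_bend = (k\_c/2) Σ (2H)² dA with dA the
metric area element per node. No measured bending rigidity is assumed: the
default k\_c is 30 k\_BT at 310 K (≈ 18.5 kcal mol⁻¹), a textbook value
for a fluid phosphatidylcholine bilayer, and every reported F\_bend carries
its k\_c. `sphere_test_mesh` provides a closed-surface harness that
bypasses the Monge gauge (exact H = 1/R and patch areas summing to 4πR²),
for which F\_bend = 8πk\_c independent of radius. The discrete operators
are validated against 1D quadrature of the closed-form integrands on an
analytically sampled sinusoid (`synthetic_height_field`); the
particle-based bent-bilayer fixture is additionally checked end to end at a
looser tolerance, since binning head positions displaced along the local
normal adds a fixture artefact of order (2πA/λ)(t/2) that is not an
operator error.

## Umbrella sampling and WHAM

Windows are inclusive arithmetic sequences of centres (`generate_windows`);
the two study layouts are 70.5→33.5 Å and 84.5→36.5 Å at 1 Å spacing (38
and 49 windows). The harmonic bias is w(ξ) = (k/2)(ξ−q)² with k in
kcal mol⁻¹ Å⁻² — the stated "spring constant of 20" is read as including
the ½ — and a `half = FALSE` flag supports the k(ξ−q)² convention, since a
bare "spring constant" is ambiguous between the two.

`wham_solve` estimates the unbiased distribution p(ξ) and per-window
free-energy constants F\_i from the self-consistent WHAM equations

p(ξₖ) = Σᵢ nᵢₖ / Σᵢ Nᵢ exp((Fᵢ − wᵢ(ξₖ))/k\_BT),
exp(−Fᵢ/k\_BT) = Σₖ p(ξₖ) exp(−wᵢ(ξₖ)/k\_BT),

on a shared grid (default 0.2 Å bins spanning the centres ± 3σ with
σ = √(k\_BT/k)). Two numerical choices matter and are deliberate. First,
the bias Boltzmann factors are averaged exactly over each bin via the
normal CDF rather than evaluated at bin centres: at k = 20 the biased
distribution width √(k\_BT/k) ≈ 0.18 Å is smaller than the bin, and
centre-point evaluation alone distorts the recovered profile by several
tenths of a kcal mol⁻¹. Second, the fixed point is found by minimising the
equivalent convex (maximum-likelihood) objective with L-BFGS and then
polishing with direct sweeps of the equations above until the
self-consistency residual max|ΔFᵢ| falls below the tolerance (10⁻⁷
kcal mol⁻¹ by default, 10⁵ iteration cap); direct iteration alone needs on
the order of 10⁵ sweeps under the study conditions to reach the same fixed
point. The PMF W(ξ) = −k\_BT ln p(ξ) is reported only where counts exist,
anchored at its minimum, and `pmf_profile` re-anchors at any occupied bin
(by default the largest-ξ bin, the nanostructure far from the membrane);
anchoring is a pure constant shift. Raw samples and pre-binned histograms
on the same grid give identical results. Windows whose bias weight touches
no other window's occupied bins cannot be stitched and raise a
disconnected-dataset error; adjacent windows whose sample ranges do not
overlap trigger a warning.

A caveat the synthetic studies make explicit: with k = 20 kcal mol⁻¹ Å⁻²
and 1 Å window spacing, adjacent biased distributions overlap by only a
fraction of a percent, so each window-to-window free-energy stitch carries
an irreducible statistical error even for ideal independent samples, and
the accumulated profile error over ~40 windows settles near 0.2 kcal mol⁻¹
RMS at 5000 samples per window. The package's consistency tests therefore
check the monotone decrease of the error with sample count; the absolute
error floor is a property of the window layout, not of the estimator
(refining the grid tenfold changes the result by ~2%).

`sample_biased_windows` draws window samples by exact inverse-CDF sampling
of p\_i(ξ) ∝ exp(−[W(ξ)+w\_i(ξ)]/k\_BT) on a fine grid (2000 bins,
piecewise-uniform within bins). This is a deliberate replacement for
running biased dynamics: it produces independent, exactly distributed
samples, which is the correct statistical model for validating the WHAM
estimator in isolation. Real umbrella-sampling time series are
autocorrelated, so real-data error bars would be larger than anything the
synthetic suite shows.

## Electrostatic potential maps

Charges are deposited on a periodic grid (default 1 Å spacing) as Gaussians
of width σ\_g = 1 Å, each kernel renormalised on the grid so the total
deposited charge matches Σq to machine precision. Poisson's equation is
solved spectrally: φ(k) = 4πρ(k)/k² in Gaussian units with the k = 0 mode
set to zero, which is equivalent to adding a uniform neutralising
background (non-neutral frames warn) and makes the box-average potential
exactly zero. Output is converted to volts via 14.3996 V per e Å⁻¹. Slice
maps average the potential over a slab around a chosen plane and over
frames. The solver is validated against an independent Ewald summation
(short-range erf-difference over images plus a direct reciprocal-space sum)
at sub-0.1% accuracy, and for sharper features than ~2 grid cells the
smearing warning indicates aliasing. The medium is uniform (vacuum-like):
no solvent dielectric model is applied, matching the smoothed-potential
convention of grid electrostatics tools.

## Synthetic data: what it does and does not emulate

The generators produce every input class the analyses assume, with the
ground truth attached to the object so tests never re-derive it:

- `make_flat_bilayer` / `make_bent_bilayer` — toy 3-particle lipids
  (head + two tails) on a lattice, planted thickness 38 Å (the scale of an
  unperturbed POPC bilayer), optional Gaussian z-noise, and for the bent
  case a sinusoidal mid-surface with quadrature ground truth for area and
  bending energy. Head −0.5 e / upper-tail +0.5 e places a surface dipole
  that leaves the membrane interior electrostatically positive, a toy
  version of the membrane dipole potential.
- `make_planted_clusters` — lattice-filled blobs, rods, or ellipsoids of
  drug-role molecules separated by gaps larger than the contact cutoff, so
  the planted partition is exactly recoverable.
- `sample_biased_windows` — exact biased sampling from a known PMF (above).
- `make_hbond_script` — donor/acceptor pairs switched between bonded
  (2.8 Å, 170°) and broken (5 Å) geometry by Bernoulli draws whose realised
  fractions are recorded, so occupancy recovery can be asserted exactly.
- `make_da_membrane_composite` — bilayer plus hovering clusters at planted
  closest-approach distances with one scripted hydrogen bond, for
  end-to-end pipeline tests.

None of this emulates real lipid chemistry, solvent, ions beyond labelled
charges, force-field energetics, or temporal correlation. Passing tests
demonstrate that the estimators are correct on inputs satisfying their
assumptions; they do not certify behaviour on under-sampled or wrapped
real trajectories.

Default test problem sizes are deliberately modest — bilayers of a few
hundred lipids, clusters of tens of molecules, 10³–10⁴ histogram samples,
up to 5 × 10⁴ samples per umbrella window, 40³-node potential grids — which
keeps the whole validation suite around ten seconds while leaving every
tolerance meaningful.

## Known limitations

- Orthorhombic boxes only; no triclinic support.
- No cluster identity tracking across frames.
- No reweighting or uncertainty quantification on the 2D landscapes.
- WHAM is 1D; no MBAR, no replica exchange.
- Membrane analysis assumes a Monge-gauge sheet; closed or overhanging
  membranes are only supported through the generic (H, dA) bending-energy
  interface.
- PDB/DCD reading targets the subset of those formats the analyses need
  (coordinates, residues, orthorhombic CRYST1), not full format coverage.
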