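---
title: "Methods: shape, surface topology and association equilibria of oligomeric proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape, surface topology and association equilibria of oligomeric proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotopo)
```

`oligotopo` bundles, as one tested pipeline, the analyses used to
characterise a homotrimeric protein domain that dissociates into monomers:
surface fractal dimension, quadric shape fitting, residue contact-network
clustering and centrality, and the trimer–monomer dissociation equilibrium
with hydrodynamic cross-checks. This vignette records the models, their
assumptions, the tunable parameters, the numerical choices made where the
design was genuinely open, and the limits of what a green test establishes.

## Structures and SASA

PDB input is parsed record-by-record; each `MODEL` block becomes a
trajectory frame. Waters and (by default) all `HETATM` records are
stripped; hydrogens are removed under the united-atom convention. The
default van der Waals radii table, `"heavy4"` (C 1.87, N 1.65, O 1.40,
S 1.85 Å), is a united-atom set chosen because crystal structures rarely
carry hydrogens and the heavy-atom radii absorb their volume; the table is
configurable and its name is echoed in every pipeline manifest. Alternate
locations keep the highest-occupancy copy, ties broken by altloc letter —
a deterministic rule so repeated loads agree byte-for-byte. Residue
identity is `(chain, residue number, insertion code)` taken as-is; no
renumbering is ever applied.

SASA uses Shrake–Rupley with a deterministic golden-section (Fibonacci)
lattice, 960 points per atom by default. Two consequences matter:

* **Bit-stability.** There is no Monte Carlo noise; identical inputs give
  identical areas.
* **Frame canonicalisation.** A space-fixed lattice makes the estimate
  depend slightly (~0.1%) on molecular orientation. Coordinates are
  therefore first rotated into the principal axes of their covariance,
  with axis signs fixed by the third moment of the projections. For
  generic structures this makes SASA *exactly* invariant under rigid
  motion. The exception is exactly degenerate symmetry (e.g. a perfect
  C3 assembly has two equal covariance eigenvalues), where the canonical
  frame is not unique and invariance holds only to lattice resolution;
  the test suite uses asymmetric fixtures for the exact-invariance
  property.

The single-atom case is exact: a sphere of radius r probed at PR has area
4π(r + PR)², which the lattice reproduces to machine precision because no
point is ever occluded.

## Fractal dimension

Surface roughness is quantified by the probe-size scaling of SASA,
2 − FD = d log SASA / d log PR, estimated by ordinary least squares of
log SASA on log PR over the ladder PR = 1.0, 1.2, …, 2.0 Å. Natural logs
are used; the slope of a log–log regression is base-invariant when both
axes share the base. `fd = 2 - slope` holds exactly by construction, and
the regression slope is checked in the tests against the closed-form
least-squares sums.

Two points deserve emphasis:

* A *smooth* single sphere of atomic size does not give FD = 2: the
  log–log curve of 4π(r + PR)² is convex, and for r = 1.7 Å the 6-point
  ladder yields slope ≈ 0.910, FD ≈ 1.09 (R² ≈ 0.997). FD → 2 only in the
  large-radius limit (r ≫ PR), which the tests verify at r = 10⁶ Å.
  FD ≈ 2 for proteins arises from the interplay of surface curvature and
  crevices at the probe scale.
* Total SASA is used, not polar/apolar splits — the simplest reading, and
  the roughness exponent is dominated by geometry, not atom typing.

Whole-assembly FD uses all chains together; `per_chain_fd()` extracts each
chain and analyses it in isolation, so the oligomer interface counts as
solvent-accessible surface, matching the situation of a dissociated
subunit. Crystal coordinates serve as the t = 0 proxy for simulation-frame
analyses; FD values from equilibrated frames can differ by a few
hundredths, which is why the cross-implementation tolerance for reference
values is ±0.05.

## Ellipsoid fitting and spheroid reduction

The general quadric Ax² + By² + Cz² + Dxy + Exz + Fyz + Gx + Hy + Iz = 1
is fitted to coordinates by linear least squares — nine coefficients, one
linear system, no iteration. The centre is −½M⁻¹(G,H,I)ᵀ with M the
symmetric coefficient matrix; substituting the centre gives the centred
quadric yᵀMy = s with s = 1 + cᵀMc, whence radii √(s/λᵢ) and the rotation
from the eigenvectors. The fit is declared non-elliptic (with the
offending eigenvalue signs) unless all λᵢ/s > 0. Degenerate inputs
(coplanar points, < 9 points) are rejected by a rank check on the design
matrix. For noiseless points on a true ellipsoid the recovery is exact to
numerical precision (rss ≤ 1e-16·n in the tests).

Fed a *filled* cloud (all atoms of a protein), the fitted surface passes
through a mean shell of the cloud rather than its outer envelope. That is
deliberate: it reproduces the semantics of the reference analysis, which
fits atomic positions directly. Because one may also want the outer
extent, `cloud_extent_radii()` provides the complementary estimator: for a
uniform solid ellipsoid the covariance eigenvalues are (semi-axis)²/5, so
√(5λ) recovers the true semi-axes; the tests confirm the implied volume to
within 5% on a 5000-point cloud. The two estimators are kept separate on
purpose — the quadric fit is never silently inflated.

All heavy atoms are used by default (the reference analysis fed full
coordinate sets); a Cα-only mode is available via the CLI/pipeline
(`--atoms CA`).

`spheroid_summary()` averages the two most similar of the three sorted
radii into R_equatorial; the remaining axis is R_polar. Ties are broken
toward the lower-index pair after ascending sort. The shape is classed
prolate/oblate by the sign of R_polar − R_equatorial, with a 2% relative
band declared "sphere" — tighter bands would let lattice-level noise flip
the class.

## Contact networks, clustering, centrality

Edges require 4 Å < d(Cα,Cα) < 8 Å with *strict* inequalities, the window
taken literally. The 4 Å lower bound excludes sequence-adjacent residues
(consecutive Cα ≈ 3.8 Å) without any explicit bonded-pair rule; the same
criterion applies within and between chains.

The Laplacian L = D − A is decomposed with a dense symmetric eigensolver
(networks here are a few hundred nodes; sparse methods would buy nothing).
The Fiedler vector gets a deterministic sign convention (first nonzero
entry positive). Clustering with k = 2 is the sign pattern of the Fiedler
vector, zero entries assigned to the positive side (they occur only on
symmetric graphs and have no natural side). The reference method does not
specify a 3-cluster algorithm; the choice here is k-means on the (v2, v3)
spectral embedding with 50 restarts under a fixed seed, followed by
canonical relabelling (clusters numbered by their lowest node index), so
identical partitions always print identically. Disconnected networks are
an error for clustering — the zero eigenvalue is degenerate and the
Fiedler partition undefined — but allowed for betweenness, which is
computed per component.

Betweenness is raw (unnormalised) Brandes counting with fractional
splitting among equal-length shortest paths and endpoints not counted as
"crossing". Normalisation is deliberately absent: the high/medium tier
thresholds (BC > 5000, 4000 < BC ≤ 5000) are on the raw-count scale of a
~500-node trimer network and would lose meaning otherwise. The
implementation is delegated to igraph; the test suite checks it against an
independent path-counting oracle written straight from the definition, on
50 random graphs up to n = 25.

`interchain_pairing()` counts, per unordered chain pair, the edges
crossing between the chains; the asymmetry score is max/median. In a C3
trimer with symmetric interfaces the score is 1; a "two against one"
dynamic arrangement shows up as a dominant pair.

## Dissociation equilibrium

For T ⇌ 3M with Kd = [M]³/[T] (units M²), subunit mass balance gives
M + 3M³/Kd = c_tot, which has a unique positive root since the left side
is strictly increasing. The root is bracketed in [0, c_tot] (Brent solve,
then Newton polish); mass conservation holds to better than 1e-10
relative at every solved point, and fractions are subunit-mass fractions
M/c_tot, 2D/c_tot, 3T/c_tot. The extended scheme T ⇌ D + M (K1),
D ⇌ 2M (K2) adds the dimer term 2M²/K2; sending K2 → ∞ at fixed K1·K2
recovers the simple scheme to 1e-6, which is both a consistency invariant
and a regression test.

Fitting minimises Σ wᵢ(f_mᵢ − f_model(c_totᵢ))² over log10(Kd) — the
log-scale makes the 1e-20–1e-10 M² search well conditioned — via bounded
scalar optimisation; the two-constant scheme uses L-BFGS-B on
(log10 K1, log10 K2) started from the one-constant fit. Weights default
to 1 (unweighted), with per-technique weights accepted; residuals are
reported per technique tag. Confidence intervals come from case-resampling
bootstrap (200 replicates, percentile CI, fixed seed recorded in the
result). Concentrations are molar throughout. Titration inputs spanning
less than two decades are rejected: a cubic isotherm cannot be pinned from
a narrow window.

One data-hygiene note: the source material for this kind of analysis
prints concentration ranges inconsistently (mM where the surrounding text
indicates µM); the package treats the canonical titration range as
2 nM–20 µM and the generators default to it.

Hydrodynamics: for an ellipsoid of revolution with polar semi-axis a and
equatorial b, the Perrin translational friction gives

* prolate (a > b, p = b/a): R_h = a·√(1−p²) / ln[(1+√(1−p²))/p]
* oblate (a < b, p = a/b): R_h = b·√(1−p²) / arctan(√(1−p²)/p)

with the sphere limit R_h = a, and D = kB·T/(6πηR_h). The axial-ratio → 1
continuity and the bound R_h ≥ (ab²)^(1/3) (volume-equivalent radius) are
property-tested. These closed forms are a reconstruction of the standard
hydrodynamic treatment — they reproduce the published diffusion estimates
for the monomer and trimer spheroids to within the reported uncertainties
— not a transcription of any proprietary fitting code. Defaults: water at
20 °C (η = 1.002e-3 Pa·s), kB = 1.380649e-23 J/K, both configurable.

## DLS dispersity and bimodal deconvolution

The dispersity statistic is the weighted variance of the diameter
histogram over its squared weighted mean — the only dimensionally
consistent reading of the defining expression — and is invariant under
uniform diameter rescaling and weight renormalisation. The bimodal fit is
nonlinear least squares of the histogram weights (not the cumulative
distribution) against a sum of two Gaussians, with bounded parameters,
initialised from the two best-separated peaks of a lightly smoothed
histogram plus a mean ± sd split start and a few seeded restarts. The
single-Gaussian fit is always computed as a degenerate start, so the
bimodal residual can never exceed the unimodal one. On effectively
unimodal data a second component is unidentifiable — it merely splits the
peak at an arbitrary ratio — so unless the second Gaussian improves the
residual by at least 20% the single-component solution is reported with
all area in the dominant component. Components are labelled
monomer/trimer by ascending mean diameter.

## Synthetic data: what it emulates, and what it does not

The generators state a fixed world and the tests probe the pipeline inside
it:

* `gen_ellipsoid_cloud()` — area-uniform surface sampling (rejection on
  the sphere-to-ellipsoid area element) or volume-uniform filling, with
  optional isotropic noise. Default fixture radii follow the fitted
  monomer axes (17.4, 20.7, 26.9 Å).
* `gen_bead_trimer()` — three copies of a compact self-avoiding Cα walk
  (step exactly 3.8 Å, excluded volume 4 Å, centroid pull to a globule of
  radius ≈ 4n^⅓ Å) arranged as a triangle; pair separations, vertical
  offsets and spins are tuned by a seeded search until achieved
  inter-chain contact counts sit within ±20% of target. Exact planting is
  over-constrained in 3-D, so achieved counts are the ground truth.
  Symmetric requests use an exact C3 construction (the same template
  rotated by 120°), making the three pair counts identical and the
  asymmetry score exactly 1. A compact globule is essential: an extended
  chain is path-like, its internal min-cut is cheaper than its interfaces,
  and no spectral method could (or should) recover it as a cluster.
* `gen_titration()` — monomer fractions on the model curve plus truncated
  Gaussian noise (default emulation: 12 log-spaced concentrations,
  2 nM–20 µM, sd 0.03 on the fraction).
* `gen_size_distribution()` — binned Gaussian-mixture densities scaled to
  percent.

What the generators do *not* emulate: real MD dynamics (frames here are
static or rigidly perturbed), SANS form factors, experimental DLS
deconvolution artefacts, correlated (non-Gaussian) titration noise, or
missing residues/altloc pathology beyond the synthetic fixtures. A green
test therefore establishes algorithmic correctness against stated ground
truth and closed forms — not agreement with any particular experimental
dataset. The one reference-structure check (surface FD of the crystal
trimer) requires the actual PDB entry and is reported as failing, with an
explanation, when that file is not available.

## Determinism and seeds

Every stochastic component (generators, k-means restarts, bootstrap,
bimodal restarts) takes an explicit integer seed, runs under a temporarily
seeded RNG and restores the caller's RNG state. Identical generator specs
give byte-identical output; re-running a pipeline config reproduces
identical files.

## Known limitations

* mmCIF input is not implemented; multi-model PDB covers the intended
  trajectory use (engine-native formats like xtc/trr are out of scope).
* SASA rigid-motion invariance is exact only for structures with a
  non-degenerate covariance spectrum (see above).
* The bead-trimer contact search is heuristic; extreme contact requests
  (e.g. thousands of contacts between small chains) fail with an
  "infeasible" error rather than distorting the geometry.
* The dimer-containing equilibrium fit is exposed and tested for
  consistency, but with typical titration data (monomer fraction only)
  K1 and K2 are weakly identified; treat the split as exploratory.
* Betweenness tiers use fixed raw-count thresholds meaningful for
  ~500-node trimer networks; for much smaller or larger networks the
  thresholds should be overridden.
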