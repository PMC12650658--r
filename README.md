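# oligotopo

Topological and biophysical analysis of oligomeric protein assemblies in R.

Many signalling proteins work as homo-oligomers whose subunits can
dissociate, and the balance between the assembled and free forms is itself a
regulatory switch. Characterising such a system means answering several
linked questions at once: how rough is the protein surface and how does it
change between the assembled and free forms; what overall shape does each
species have; which residues wire the subunits together; and where does the
monomer–oligomer equilibrium sit at a given concentration. `oligotopo`
implements one tested pipeline for all of these, aimed at structural
biophysicists who have coordinates (crystal structures or MD frames) plus
solution data (titrations, DLS histograms) for a trimer-forming domain.

## What it computes

**Surface fractal dimension.** The solvent-accessible surface area (SASA,
deterministic Shrake–Rupley) is evaluated over a ladder of probe radii
PR = 1.0–2.0 Å and the roughness exponent follows from the scaling law

    2 − FD = d log SASA / d log PR

by linear regression of log SASA on log PR. Smooth surfaces give FD → 2;
globular proteins typically fall in 1.7–2.3. Whole assemblies and isolated
chains (buried interface exposed) are analysed with `fractal_dimension()`
and `per_chain_fd()`.

**Ellipsoid shape fitting.** The general 9-coefficient quadric

    Ax² + By² + Cz² + Dxy + Exz + Fyz + Gx + Hy + Iz = 1

is fitted to atomic coordinates by linear least squares
(`fit_ellipsoid()`); centre, semi-axes and rotation follow from the
eigen-decomposition of the centred quadric. `spheroid_summary()` reduces
the three axes to a polar/equatorial spheroid by averaging the two most
similar radii, classifying the shape as prolate (rugby ball) or oblate
(disk).

**Protein contact networks.** Residues are nodes; edges join Cα pairs with
4 Å < d < 8 Å (`build_network()`). The graph Laplacian L = D − A yields the
Fiedler vector for 2-way spectral partitioning and a (v2, v3) k-means
embedding for 3 clusters (`spectral_clusters()`); raw Brandes betweenness
centrality with high/medium tiers (BC > 5000, 4000 < BC ≤ 5000) flags the
residues carrying inter-subunit communication
(`betweenness_centrality()`), and `interchain_pairing()` quantifies 2:1
dynamic asymmetry between chains.

**Dissociation equilibrium.** For a trimer T of subunits M, the T ⇌ 3M
model with Kd = [M]³/[T] (units M²) — optionally extended through a dimer
intermediate, T ⇌ D + M ⇌ 3M — is solved for species fractions at any total
subunit concentration (`species_fractions()`) and fitted to titration data
(`fit_dissociation()`, bootstrap CIs). `perrin_hydro()` converts fitted
spheroids to hydrodynamic radii via Perrin friction factors and to
translational diffusion coefficients via Stokes–Einstein,
D = kB·T/(6πηRh).

**DLS dispersity.** `dispersity()` computes the weighted variance of a
hydrodynamic diameter distribution over its squared mean;
`fit_bimodal()` deconvolves bimodal histograms into monomer/trimer
Gaussian components.

Every stage has a synthetic-data generator (`gen_ellipsoid_cloud()`,
`gen_bead_trimer()`, `gen_titration()`, `gen_size_distribution()`) that
attaches machine-readable ground truth, so the whole pipeline is testable
without any external downloads.

## Worked example

```r
library(oligotopo)

# Where does the trimer-monomer equilibrium sit, using the fitted
# dissociation constant Kd = 5.2e-16 M^2?
m <- equilibrium_model("T3M", kd = 5.2e-16)
species_fractions(m, 4.0e-8)
#> <species_fractions> c_tot = 4e-08 M (T3M): monomer 40.2%, dimer 0.0%, trimer 59.8%
species_fractions(m, 6.0e-9)
#> <species_fractions> c_tot = 6e-09 M (T3M): monomer 86.5%, dimer 0.0%, trimer 13.5%
```

At 40 nM total subunit the trimer already carries ~60% of the mass, while
at 6 nM the protein is essentially dissociated — a ten-fold concentration
change flips the dominant species.

```r
# Shape: reduce fitted semi-axes to a polar/equatorial spheroid and predict
# the diffusion coefficient each species should show in solution.
spheroid_summary(c(26.9, 17.4, 20.7))   # monomer axes from an MD-frame fit
#> <spheroid_summary> prolate: R_polar 26.90 A, R_equatorial 19.05 A
perrin_hydro(24, 17.6, temperature = 293)    # monomer spheroid (scattering fit)
#> <hydro_spheroid> prolate (24.0 x 17.6 A): R_h = 19.69 A, D = 108.8 um^2/s at 293.0 K
perrin_hydro(20, 41.3, temperature = 293)    # trimer disk
#> <hydro_spheroid> oblate (20.0 x 41.3 A): R_h = 33.92 A, D = 63.1 um^2/s at 293.0 K
```

The predicted 108.8 and 63.1 µm²/s bracket what fluorescence correlation
experiments report for the free and assembled species (≈110 and ≈64 µm²/s).

```r
# Contact-network topology on a synthetic trimer with a planted 2:1
# chain-pairing asymmetry.
g <- gen_bead_trimer(30, c(AB = 20, AC = 5, BC = 5), seed = 7)
net <- build_network(g$model)
net
#> <contact_network> 90 residues, 327 edges, chains: ABC, window (4, 8) A
interchain_pairing(net)$counts
#> A:B A:C B:C
#>  23   5   5
spectral_clusters(net, k = 3, seed = 1)
#> <cluster_partition> k = 3, sizes: 29/31/30, algebraic connectivity 0.1863
```

Chains A and B share four times more contacts than either does with C —
the planted "two against one" arrangement — and the three spectral
clusters recover the three chains.

## Pipeline and CLI

`run_pipeline("config.json")` executes the configured stages and writes
per-stage CSV/JSON plus a `manifest.json` (seeds, radii table, resolved
config). The same functionality is scriptable via the installed
`inst/exec/oligotopo` entry point or `oligotopo_main()`:

```sh
oligotopo fd INPUT.pdb --per-chain --probes 1.0:2.0:0.2
oligotopo ellipsoid INPUT.pdb --atoms CA
oligotopo pcn INPUT.pdb --k 3 --bc
oligotopo equilibrium predict --kd 5.2e-16 --conc 4e-8
oligotopo hydro --polar 24 --equatorial 17.6 --temp 293
oligotopo simulate titration --seed 2 --o out/
oligotopo run config.json
```

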