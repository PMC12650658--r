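Package: oligotopo
Title: Topological and Biophysical Analysis of Oligomeric Protein Assemblies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the shape, surface topology and
    association equilibria of oligomeric proteins from atomic coordinates and
    solution data. Includes a multi-model PDB reader, deterministic
    Shrake-Rupley solvent-accessible surface areas, surface fractal dimension
    from SASA-probe-radius scaling, general nine-coefficient ellipsoid fitting
    with prolate/oblate spheroid reduction, residue contact networks with
    Fiedler-vector spectral clustering and betweenness centrality,
    monomer-dimer-trimer dissociation-equilibrium solving and fitting,
    Perrin/Stokes-Einstein hydrodynamic predictions, dynamic-light-scattering
    dispersity and bimodal deconvolution, synthetic-data generators for every
    stage, and a pipeline runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
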