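Package: memmorph
Title: Membrane Remodeling Analysis: Shape Fields, Multi-Map Free Energies,
    and Protein-Lipid Interface Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of protein-induced membrane remodeling
    from particle-based bilayer configurations. Computes mid-plane deflection,
    thickness and lipid-tail order-parameter maps with replicate standard
    errors; implements the Multi-Map collective variable over labeled density
    maps, harmonic umbrella biasing, a Fourier-space Helfrich-Canham Monte
    Carlo surrogate sampler, and WHAM reconstruction of potentials of mean
    force; scores the polar/hydrophobic solvation cost of membrane bending per
    residue from solvent-accessible surface areas under two hydrophobicity
    scales; detects direct and water-mediated protein-lipid hydrogen bonds;
    and filters and clusters evolutionary-coupling residue pairs at the lipid
    interface. Includes synthetic generators for bilayers draped on height
    fields, toy multi-sphere proteins, and coupling tables with planted
    clusters, plus a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    bio3d
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
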