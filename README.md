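# memmorph

Quantitative analysis of protein-induced membrane remodeling, for people who
simulate membrane proteins and need to (i) *measure* how a bilayer deforms
around a protein and (ii) *price* that deformation in free energy.

Membrane transporters that move a domain vertically through the bilayer (the
"elevator" architecture) can drag the surrounding membrane with it, bending
the mid-plane by around 10 Å over distances of ~100 Å. `memmorph`
implements the analysis machinery such a study needs as one tested R
package:

* **Shape and order fields** from labeled particle configurations:
  mid-plane deflection maps (far-field zero level), bilayer thickness maps,
  second-rank tail order parameter P2 = (3⟨cos²θ⟩ − 1)/2 per leaflet,
  alkyl-chain density shells around a protein, radial cross-sections,
  lipid-shell exchange counts, per-domain vertical offsets, and replicate
  standard errors.
* **Free-energy machinery**: a similarity ("Multi-Map") collective variable
  ξ over a family of labeled 3D density maps, ξ = Σₖ ξₖSₖ / ΣₖSₖ with
  Sₖ the overlap of the configuration with map k; harmonic umbrella
  biasing; a Fourier-space Monte Carlo sampler of the Helfrich–Canham
  energy E = Σ_q (A/2)(κq⁴ + σq²)|h_q|² serving as the configuration
  source; and WHAM reconstruction of the potential of mean force with
  block-bootstrap errors.
* **Solvation ledger**: Shrake–Rupley SASA (deterministic Fibonacci point
  set, 1.4 Å probe), membrane-slab occlusion for flat vs deformed membrane
  states, GXG reference areas, and the per-residue transfer score
  δG_sol(i) = S_transfer(i) · [A_flat(i) − A_bent(i)] / A_max(i)
  under two shipped hydrophobicity scales, with the
  "≥ 1 k_BT under both scales" classification rule.
* **Interface evidence**: direct and water-mediated protein–lipid
  hydrogen-bond occupancies, and filtering + clustering of
  evolutionary-coupling residue pairs (probability > 0.5, sequence
  separation ≥ 8, lipid H-bond anchor, no buried/vestibule members).
* **Synthetic generators** for all of the above: bilayers draped on
  prescribed or thermally fluctuating height fields, toy multi-sphere
  proteins, and coupling tables with planted clusters — so every stage is
  testable end to end without any external data.

## Worked example

Drape a noisy bilayer over a 10 Å depression, recover the deformation, and
price it:

```r
library(memmorph)

surf   <- gaussian_bump_field(32, 160, amplitude = -10, width = 25)
spec   <- bilayer_spec(900, 160, vertical_noise_sd = 1, seed = 1)
frames <- lapply(1:3, function(f) {
  s <- spec; s$seed <- f
  generate_bilayer(s, surf)
})

defl <- midplane_deflection(frames, spacing = 8, far_field_radius = 60)
round(min(defl$values, na.rm = TRUE), 1)   # deepest deflection
#> [1] -9.8

# price the same family of shapes with umbrella sampling + WHAM
base <- gaussian_bump_field(16, 160, amplitude = 1, width = 28)
maps <- build_target_maps(base, seq(-4, 14, length.out = 10))
prm  <- helfrich_params(kappa = 15, sigma = 0, grid_n = 16, box_l = 160,
                        n_sweeps = 400, seed = 1)
w    <- run_umbrella(prm, maps, default_window_plan(1, 9, 12),
                     force_constant = 10, burn_in = 80, seed = 1)
pmf  <- wham_pmf(w, bins = 30, n_boot = 10, seed = 1)
pmf
#> <pmf_curve> 30 bins over xi in [0.4407, 9.484]
#>   max free energy 4.79 kcal/mol; mean stderr 0.257 kcal/mol; converged: TRUE
```

The deflection map recovers the −10 Å depression the generator prescribed
(−9.8 Å at 8 Å resolution with 1 Å vertical noise), and the PMF says that
driving this desk-scale membrane patch (κ = 15 kcal/mol, 160 Å box) to a
10 Å deformation costs ≈ 4 kcal/mol, rising when lateral tension is
applied. `plot(pmf)` draws the curve with its bootstrap error bars.

The one-command synthetic demo writes every stage artifact plus a manifest
with checksums:

```r
run_pipeline(default_pipeline_config(outdir = "demo", seed = 1))
```

A thin shell front end for the same entry points ships in
`inst/scripts/memmorph`.

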