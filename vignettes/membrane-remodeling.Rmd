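---
title: "Measuring and pricing membrane deformations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and pricing membrane deformations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memmorph)
```

`memmorph` analyses how membrane proteins reshape the surrounding lipid
bilayer and what that reshaping costs. This vignette documents the models,
the numerical choices and their rationale, and what the synthetic test bed
does and does not establish about real simulation data.

## The measurement side: shape fields from particle configurations

The universal input is a `membrane_frame`: labeled lipid particles (lipid
id, leaflet, head/tail role, coordinates in Å) plus optional protein
particles with domain tags. From frames the package computes:

* **Mid-plane deflection**: per grid cell (half-open cells, default 5 Å),
  the mid-plane is the midpoint between the mean upper-leaflet and mean
  lower-leaflet head heights. The midpoint-of-cell-means definition (rather
  than per-lipid pairing) is robust when leaflet populations differ per
  cell. The zero level is the mean over all cells beyond a far-field
  radius (default 200 Å, shrunk to 40 % of the box when smaller) from the
  protein centre, so rigidly translating the system in z changes nothing.
  Positive values are outward deflections.
* **Thickness**: per-cell distance between the two head surfaces. Bending a
  bilayer moves both leaflets together, so a pure bend leaves this map
  flat — the diagnostic that separates bending from thinning.
* **Tail order**: P2 = (3⟨cos²θ⟩ − 1)/2 with θ between each lipid's
  head-to-farthest-tail-bead vector and the global membrane normal; +1 for
  tails along the normal, −0.5 in-plane, 0 isotropic. Computed per leaflet
  because curvature tilts the two leaflets differently.
* Alkyl density shells near the protein, radial cross-sections against the
  protein's in-plane footprint (a deterministic stand-in for "distance to
  the protein surface", which is otherwise ill-defined on a grid), shell
  residence/exchange counts, per-domain vertical offsets against the same
  far-field zero, and per-cell replicate standard errors with the map-wide
  average as summary.

Cells without observations are flagged empty (`NA` with count 0), never
silently zero. In-plane distances use minimum-image conventions; maps treat
coordinates as half-open cells `[x, x + spacing)`.

## The pricing side: a Helfrich–Canham surrogate plus biased sampling

Pricing a deformation needs an ensemble, and molecular dynamics is out of
scope; instead the package samples the membrane mid-plane directly from the
Helfrich–Canham energy in Monge gauge,

$$E[h] = \sum_q \frac{A}{2}\,\big(\kappa q^4 + \sigma q^2\big)\,|h_q|^2,$$

with bending modulus κ (kcal/mol), tension σ (supplied in mN/m and
converted by the exact factor 1 mN/m = 1.4393 × 10⁻³ kcal/mol/Å², derived
from Avogadro's number and the thermochemical calorie), projected area A
and continuum wavevectors q = 2πn/L. κ defaults to nothing: it is an input,
because the appropriate value depends on the force field or membrane being
emulated; 10–20 kcal/mol (≈ 17–34 k_BT) spans common phospholipid bilayers.
Thermal constants come from one table (`memmorph_constants()`;
k_BT = 0.5925 kcal/mol at 298.15 K).

Unbiased sampling draws each Fourier amplitude from its exact stationary
Gaussian, so equipartition ⟨|h_q|²⟩ = k_BT/[A(κq⁴ + σq²)] holds by
construction and is verified by test. Under a bias the sampler turns into
Metropolis Monte Carlo with three move types per sweep: a collective move
along the target deformation shape (without it, no local scheme reaches
amplitudes far outside the thermal range in reasonable time), Gaussian
random walks on the low-|q| modes that carry the large-scale shape
(acceptance on the full analytic Helfrich + bias energy change), and one
block refresh of all remaining modes drawn from their unbiased Gaussians
and accepted on the bias change alone — exact, because the Gaussian factor
cancels in the Metropolis ratio. Correctness is tested by running the
biased machinery with a negligible force constant and recovering
equipartition.

## The similarity variable and its conditioning

The collective variable scores how closely a configuration matches a
family of target density maps φ_k with labels ξ_k (the deformation
amplitudes):

$$\xi = \frac{\sum_k \xi_k S_k}{\sum_k S_k},\qquad
  S_k = \sum_i \phi_k(r_i),$$

by trilinear interpolation at the contributing points — head beads for
particle frames, grid-node surface samples for height fields. The
functional form lives in one function (`multimap_xi`) so an alternative
similarity kernel can be swapped without touching the samplers.

Maps are Gaussian-smeared occupancies of the surfaces a_k·h_base(x, y).
Two conditioning choices matter and are defaults for a reason:

* **Support restriction** (`support_threshold`, default 0.5): columns where
  the base deformation is negligible are zeroed in every map. Where all
  target surfaces coincide, every map accrues identical overlap, which
  only dilutes ξ toward the label mean; masking those columns restores
  amplitude discrimination.
* **Smearing width** (default 0.6 × the vertical separation of adjacent
  target surfaces): neighbouring maps must overlap for ξ to vary smoothly,
  but much wider smearing washes out their contrast.

One further choice is essential for interpreting the PMF: **the map family
should extend beyond the window range actually sampled** (the shipped demo
uses maps at −0.4…1.4 times the maximum amplitude for windows at
0.1…0.9 times it). Inside that range the label-weighted Gaussian comb is a
partition of unity and ξ is, to good accuracy, a *linear* functional of the
surface. For a Gaussian (Helfrich) model with a linear variable, the
free-energy profile equals the bending energy of the constrained-mean
surface up to a constant — the identity the self-consistency checks
exploit. With an unpadded family the sampled configurations hit the comb
edge, ξ becomes nonlinear there, and the PMF acquires a real
noise-selection (entropic) contribution that the mean-surface energy does
not contain; this is a property of the variable, not an error of WHAM or
of the sampler, and the padded family is how the package avoids it.

## Umbrella sampling and WHAM

Windows apply U = ½k(ξ − ξ₀)². The default plan divides the target range
into 61 windows — the convention for production-scale studies of this kind
— but every desk-scale run here uses far fewer (typically 12), which the
demo configs state explicitly. Adjacent-window histogram overlap below 1 %
of samples triggers a warning. WHAM solves the standard self-consistent
equations by direct iteration in log space (tolerance 10⁻⁷ kcal/mol on the
window shifts, half-open bins with ties to the lower bin, empty bins
masked), anchors the PMF at zero at its minimum, and reports per-bin
standard errors from a block bootstrap over each window's series (5 blocks,
10–20 replicates by default). A single unbiased window degenerates to
−k_BT ln(histogram), which is tested literally, and closed-form harmonic
and double-well oracles bound the reconstruction error (curvature within
5 %; barrier within bootstrap error of a quadrature reference).

## The solvation ledger

The polar/hydrophobic cost of keeping the membrane flat versus letting it
bend is scored per residue as

$$\delta G_{sol}(i) = S_{transfer}(i)\,
  \frac{A_{flat}(i) - A_{bent}(i)}{A_{max}(i)},$$

negative when the deformed membrane state is favoured. Areas are
Shrake–Rupley SASA with a 1.4 Å probe and a deterministic Fibonacci point
set (default 960 points — no RNG in any area); the membrane is a
solvent-excluded slab of total width 16 Å (half-thickness 8 Å), either
flat at a level or following a height field, and surface points inside it
count as occluded. The flat counterpart of a deformed membrane is aligned
by matching the mean deformed-surface height over an alignment mask (the
cells under the anchoring domain), a deterministic stand-in for alignment
done by eye. A_max is the residue's SASA fully exposed in an extended GXG
tripeptide built by the same engine; the template geometry is synthetic
(extended backbone, zigzag side chain), which is adequate because A_max
only normalizes the area difference. Atomic radii come from one embedded
Bondi-style table; hydrogens are excluded by default (a flag includes
them).

Two hydrophobicity scales ship as data files: a whole-protein
folding-stability scale and a side-chain-analog membrane-insertion scale;
the latter lacks His, Gly and Pro, which are filled from the former, so
both cover the 20 standard types. A residue is classified as favouring one
membrane state only when |δG_sol| ≥ 1 k_BT under *both* scales with the
same sign (k_BT at 323 K by default, the typical temperature of the
atomistic snapshots this analysis targets; configurable). Totals are exact
sums of the per-residue values.

## Interface evidence

Hydrogen bonds use conventional geometry — donor–acceptor distance
≤ 3.5 Å plus a D–H–A angle ≥ 120° whenever explicit hydrogens exist; for
hydrogen-free (coarse-grained) input the angle criterion is skipped with a
message. A water-mediated interaction is a single water H-bonded to both a
protein side chain and a lipid in the same frame (two-water bridges are
out of scope); a pair already counted direct is not double-counted
mediated. Occupancy is the fraction of frames with at least one qualifying
event per side chain, counting each frame once.

Coupling analysis consumes externally inferred residue-pair tables
(CSV: i, j, score, probability). Retention requires probability
strictly > 0.5, sequence separation |i − j| ≥ 8 ("less than eight apart"
excluded, read literally — about two helix turns), at least one member
annotated as a lipid H-bond anchor, and no buried or vestibule-only
member. Burial calls are user-supplied annotations (optionally derived
from relative SASA) because they are structural judgments, not something
this package infers. Clusters are connected components of the
residue-sharing graph, numbered by smallest member residue so the result
is independent of input order. The fraction of input pairs retained is
reported as a descriptive statistic only.

## The synthetic test bed: what it shows and what it does not

The generators produce bilayers of one head and ≥ 1 tail beads per lipid
on a jittered square lattice per leaflet (uniform coverage without a
packing algorithm), draped on prescribed surfaces with rigid per-lipid
vertical Gaussian noise; toy multi-sphere proteins; and coupling tables
whose planted clusters satisfy the retention rules while decoys fail
exactly one of them. Defaults mirror the conditions of the study type this
package serves: a 16 Å hydrophobic slab, ~10 Å deformation depths,
tensions of 0–10 mN/m, production-scale geometry of ~7500 lipids in a
~500 Å box (tests verify that scale is generated correctly, while running
analyses on smaller boxes), K = 10 target maps and a 61-window plan as the
reference configuration.

The desk-scale problem sizes used throughout — 16–32 grid nodes, 160 Å
boxes, hundreds of lipids, 400 sweeps and 12 windows per PMF — were chosen
so the whole suite, including the acceptance script, completes in minutes;
they are stated in the configs rather than buried in code. What passing
tests establish: the estimators are unbiased against their generators, the
sampler is exact against equipartition, WHAM is accurate against closed
forms, and the Multi-Map PMF of the surrogate reproduces the surrogate's
own bending energetics. What they do not establish: anything about
force-field accuracy, lipid-specific chemistry, protein flexibility, or
the magnitude of real membrane deformation costs — those require the
molecular simulations this package analyses, not the surrogate it ships.

## Known limitations

* The Monge-gauge surrogate cannot represent overhangs, pores, or bilayer
  compressibility; thickness is an observable here, not a degree of
  freedom.
* ξ is evaluated on head beads (or surface nodes); lipid-resolved map
  variables (e.g. per-leaflet maps) are not implemented.
* The SASA engine is O(atoms × neighbours × points) R code: fine for
  single structures and the ledger's two membrane states, not tuned for
  trajectories.
* GRO/PDB output carries labels in a sidecar CSV because those formats
  cannot hold leaflet/role metadata.
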