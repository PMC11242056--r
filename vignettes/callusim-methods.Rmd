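---
title: "Mechano-regulated fracture-healing simulation: model and methods"
author: "callusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-regulated fracture-healing simulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the simulator models

`callusim` is a desk-scale digital twin of a fixed long-bone shaft
fracture.  Secondary bone healing is driven by the mechanical environment
of the fracture gap and by revascularization of the injured region: small
interfragmentary strains promote direct (intramembranous) bone formation,
moderate compressive strains drive a cartilage intermediate (endochondral
ossification), excessive strains destroy tissue, and prolonged
understimulation resorbs it.  The package couples

1. a voxel finite-element model of a nailed tibial or femoral diaphysis
   (`build_scenario()`, `solve_displacements()`, `compute_strains()`),
2. fuzzy mechano-regulation rules in the Claes-Heigele tradition that
   advance the per-cell tissue composition (lamellar bone, woven bone,
   cartilage, fibrous tissue) and vascularity once per simulated day
   (`fuzzify()`, `update_vascularity()`, `update_tissues()`), and
3. a per-quadrant path search for cortical bridging by lamellar bone that
   classifies the case as union when at least three of the four anatomical
   quadrants are simultaneously bridged within the simulated horizon
   (default 240 days; `is_bridged()`, `classify_outcome()`).

A typical session:

```{r example}
library(callusim)
run <- simulate_healing(tibia_shaft_config())
run$report          # outcome, consolidation day
weight_bearing_sweep(femur_wedge_config(), levels = c(1, 0.10, 0.05))
```

## The scenario generator is the study population

Patient CT geometry is not an input: the generator builds an idealized
hollow-cylinder diaphysis with an intramedullary nail, a fracture gap of
configurable morphology (transverse, oblique, or a wedge with an
interposed fragment), and a periosteal "healing domain" annulus in which
tissue differentiation is simulated.  The idealization preserves the
mechanical determinants the healing model responds to — gap size, nail
fit, fixation stiffness, fragment topology, loading — and deliberately
omits everything else (muscle-level load sets, bone-density
heterogeneity, the fibula, contact and large-deformation mechanics).
Simulated outcomes therefore support conclusions about the *mechanics and
biology of the construct*, not about any individual patient anatomy.

Two case-analog presets ship with the package:

* `tibia_shaft_config()` — transverse tibial shaft fracture, 2 mm gap,
  10 mm reamed nail, full weight-bearing (the mechanically driven case);
* `femur_wedge_config()` — femoral shaft fracture with a laterally based,
  initially devascularized interposed wedge fragment and a 12 mm nail
  (the biologically driven case).

Defaults chosen where no source states a value, fixed once and not
revisited: body weight 800 N; cortex 24/5 mm (tibia) and 26/6 mm (femur)
with reamed canals 1 mm over the nail diameter; healing-domain axial
margin 1.5 x gap width and callus diameter 1.4 x outer diameter; voxel
size 1.5 mm for the case-analog scenarios.

### Fixation representation

All material interfaces share mesh nodes; there is no contact mechanics.
Three consequences follow and are handled explicitly:

* the nail-bone clearance must be resolved by at least one voxel of soft
  medullary tissue, and any bone or callus voxel sharing even a corner
  node with a nail voxel is relabeled as canal — otherwise spurious voxel
  corner contacts couple nail and tissue rigidly.  This layer doubles as
  the physical sliding interface of a smooth implant: tissue does not
  osseointegrate onto the nail, so maturing callus must transmit load
  through the fracture zone and the cortices rather than shortcut through
  the implant (which would permanently stress-shield the zone ends);
* interlocking is represented by two canal-ring bands (default 8 mm at
  either segment end) of a compliant "locking interface" material
  (`E_locking`, default 1000 MPa, cancellous-bone order).  Rigid bonding
  would make the construct orders of magnitude stiffer than mechanical
  testing of locked nail constructs supports; the default puts the axial
  stiffness of the stable 10 mm tibial construct at a few 1e4 N/mm and
  the day-1 interfragmentary strain (~2-3%) in the intramembranous
  window, which is what a "stable locked nail under full weight-bearing"
  means in this model family.  A *destabilized* fixation is modeled by
  scaling the implant-system moduli (nail and locking interface)
  together, since the interface compliance stands for load transfer
  through the implant's own screws;
* the distal base is fully clamped and loads enter through
  tributary-area-weighted nodal forces on the proximal surface (medial
  55% / lateral 45% of 2.2 x body weight for the tibia; a single
  resultant of 2.38 x body weight for the femur), applied as the static
  daily peak of the gait cycle.

## Daily update

Each simulated day executes: tissue mixture -> element properties
(linear rule of mixtures by default, exponent configurable) -> linear
elasticity solve on trilinear hexahedra -> distortional (octahedral
shear) and dilatational (volumetric) strain per cell -> trapezoidal fuzzy
memberships -> vascular front update -> rate-scaled tissue transfers.

The strain windows (distortional breakpoints 0.0005 / 0.05 / 0.15 / 0.30
with 20% crossfade shoulders; dilatational compression threshold -0.002)
and the per-day rates (woven formation 0.03, chondrogenesis 0.05,
endochondral ossification 0.04, remodeling 0.02, atrophy 0.01,
destruction 0.10, vascular front 0.3 mm/day, angiogenesis limit 0.06,
ossification vascularity gate 0.5) live in `fuzzy_rules()` and round-trip
through the YAML configuration, so the whole rule base is swappable.
Inference is Mamdani-style: min for conjunction, additive aggregation of
rule outflows, outflows capped so fractions remain a partition of unity.
The update is an explicit forward-Euler day step; with all default rates
well below 1/day and capped transfers, it is unconditionally stable and
conserves the per-cell fraction sum exactly (to accumulation rounding,
< 1e-9 over 240 days).

Two emergent regimes are worth knowing about when interpreting outputs:

* *Homeostatic equilibrium.*  Once the callus consolidates, strains fall;
  if they fall below the understimulation floor the atrophy rule resorbs
  tissue until the strain returns to the floor.  Long simulations
  therefore settle near the floor strain with a stationary tissue mix —
  the model's version of load-adaptive maintenance.  Union is defined by
  the first day three quadrants bridge, so a later drift around the
  homeostatic point does not retract a union verdict.
* *Avascular trap.*  Cells held above the angiogenesis strain limit never
  vascularize, so neither intramembranous nor endochondral ossification
  can proceed there no matter how much cartilage accumulates.  This is
  what keeps a destabilized construct in non-union: the gap plane stays
  above the limit, only cartilage (which barely stiffens the construct)
  can form, and the near-gap cortex — shielded by the soft gap — resorbs
  under understimulation, which progressively increases the axial
  deviation under the asymmetric medial/lateral load split.

## Numerical choices

* Reduced free-DOF system assembled on a precomputed sparse pattern; the
  element matrix separates as `ke = lambda*Kl + mu*Km`, so daily
  reassembly is a fused multiply-add (C++ kernel).
* CHOLMOD supernodal Cholesky; inside the daily loop the most recent
  factorization preconditions a conjugate-gradient iteration warm-started
  from the previous day, refreshed when convergence to the equilibrium
  tolerance (relative residual 1e-8) needs more than 30 iterations.
  Results are bit-reproducible for a fixed configuration.
* Strain invariants are computed from the centroid strain tensor via
  principal invariants, avoiding per-cell eigendecompositions.
* Quadrants are 90-degree azimuthal sectors about each slice centroid,
  centered on the anatomical axes (+x anterior, +y medial; z is the bone
  axis, distal at z = 0); boundary ties go to anterior, then medial.
* Bridging uses face (6-)connectivity on lamellar fraction >= 0.5 by
  default — a shared face is a load path; 26-connectivity and other
  thresholds are flags.
* Degenerate inputs: a zero gap yields an intact (bridged) cortex; zero
  weight-bearing yields a zero strain field (no solve); floating
  fragments (no soft-tissue connection to the fixed base) abort the solve
  with a diagnostic naming the fragment.

## Problem sizes and runtime

The case-analog scenarios discretize to roughly 23 x 23 x 28 (tibia) and
25 x 25 x 31 (femur) cells at 1.5 mm, i.e. 1e4-2e4 free degrees of
freedom, chosen so a full 240-day course runs in a couple of minutes on
one core.  The conservation checks in the test suite use a 16 x 16 x 32
grid at 2 mm.  Halving the voxel size quadruples per-day cost; the
qualitative outcomes (union/non-union, bridging order) are stable across
these resolutions, while consolidation days shift by days-to-weeks, so
absolute day counts should be read as model time, not calendar
predictions.

## Known limitations

* Fragment geometry is never updated: progressive malalignment appears as
  a rising angulation metric computed from the displacement field, not as
  an actual secondary dislocation of the mesh.
* The locking interface, marrow, and nail are linear elastic and bonded;
  screw loosening, toggle, and contact nonlinearity are out of scope.
* Biology beyond the vascularity proxy (growth factors, comorbidities,
  smoking, infection) is not modeled; the devascularized-fragment flag is
  the only biological insult available.
* The fuzzy rule constants are model defaults of this artifact, not
  measured quantities; conclusions should rest on comparisons between
  scenarios run under the same rule set, which is how the package's
  acceptance checks use them.
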