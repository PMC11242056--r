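# callusim

Desk-scale simulation of bone-healing after intramedullary nailing of a
long-bone shaft fracture, for researchers in musculoskeletal
mechanobiology and computational orthopaedics who want a fully
self-contained, reproducible stand-in for patient-specific
fracture-healing workflows.

A voxelized digital twin of the fixed fracture — hollow-cylinder
diaphysis, nail, fracture gap, periosteal callus ("healing domain") — is
loaded once per simulated day with the peak gait-cycle force (tibia:
2.2 × BW split 55/45 over the medial/lateral plateau; femur: 2.38 × BW
resultant), scaled by the weight-bearing fraction.  A trilinear-hexahedron
linear elasticity solve yields the two mechano-regulation stimuli per
cell,

* distortional strain  γ = (2/3)·√((ε₁−ε₂)² + (ε₂−ε₃)² + (ε₃−ε₁)²)
* dilatational strain  εᵥ = ε₁ + ε₂ + ε₃  (signed, negative in compression)

which drive fuzzy tissue-transfer rules in the Claes–Heigele tradition:
low distortional strain plus adequate vascularity forms woven bone from
fibrous tissue; moderate compressive strain forms cartilage; cartilage
ossifies where vascularized; woven bone remodels to lamellar bone;
understimulated tissue atrophies; excessive strain destroys formed
tissue.  Vascularity spreads as a front (0.3 mm/day) that stalls above an
angiogenesis strain limit.  Healing is scored by a path search for
connections of lamellar bone between the fragments in each anatomical
quadrant: **union** = at least three of four quadrants simultaneously
bridged within 240 days, otherwise **non-union**.

## Worked example

```r
library(callusim)

run <- simulate_healing(tibia_shaft_config(), stop_at_union = TRUE)
print(run)
#> <healing_run> tibia transverse, 71 day(s) simulated
#>   outcome: union (consolidation day 71); max simultaneous bridged quadrants: 4
```

The stabilized 10 mm-nail tibia under full weight-bearing starts at a
peak gap strain of about 2.5% — inside the intramembranous window — and
bridges all four cortices on day 71.  Destabilizing the fixation
(dividing the implant-system moduli — nail and locking interface — by
100) pushes the initial gap strain far above the formative windows, which
blocks revascularization of the gap and destroys forming tissue:

```r
run_destab <- simulate_healing(
  tibia_shaft_config(),
  table = material_table(E_nail = 1100, E_locking = 10))
run_destab$report$outcome        # "non_union"
run_destab$report$max_bridged    # quadrants ever bridged simultaneously
```

and the angulation metric (axial deviation under the asymmetric
medial/lateral load) rises over the course as the shielded bone ends
resorb.  The femoral wedge case runs the biological scenario: a
devascularized interposed fragment under 5–10% body-weight loading never
bridges and the fragment's mineralized fraction decays day after day
(atrophic dissipation), while the same construct at full weight-bearing
and with a vascularized fragment consolidates slowly within the horizon:

```r
weight_bearing_sweep(femur_wedge_config(), levels = c(1.0, 0.10, 0.05))
```

Scenario configs are plain YAML (see
`system.file("extdata", "tibia_shaft.yaml", package = "callusim")`, which
also documents every material and rule constant).  `run_simulation()`
writes a reproducible artifact directory (config snapshot, per-day CSV,
legacy-VTK field snapshots, simulated ap/ml radiograph PNGs, JSON
report), and `inst/scripts/callusim` is a command-line front end
(`simulate`, `sweep`, `render`).

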