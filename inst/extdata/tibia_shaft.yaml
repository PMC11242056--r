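# Reference configuration: stabilized transverse tibial shaft fracture
# (AO/OTA 42B-like) after reamed exchange nailing, full weight-bearing.
# All defaults of the material table and fuzzy rule set are spelled out;
# this file doubles as the package's reference config schema.
scenario:
  bone_type: tibia
  outer_diameter: 24.0          # mm
  cortical_thickness: 5.0       # mm
  canal_diameter: 11.0          # mm (reamed)
  nail_diameter: 10.0           # mm
  segment_length: 42.0          # mm modeled segment
  gap_width: 2.0                # mm
  fracture_kind: transverse
  callus_diameter: 33.6         # mm (1.4 x outer)
  axial_margin: 3.0             # mm healing domain beyond the gap, each side
  voxel_size: 1.5               # mm
  body_weight: 800.0            # N
  weight_bearing: 1.0
  days: 240
  seed: 1
  peak_multiplier: 2.38         # femoral load multiple (unused for tibia)
  lock_length: 8.0              # mm interlocking band at either end
materials:
  E_lamellar: 10000.0           # MPa
  E_woven: 4000.0
  E_cartilage: 10.0
  E_fibrous: 3.0
  nu_lamellar: 0.3
  nu_woven: 0.3
  nu_cartilage: 0.3
  nu_fibrous: 0.3
  E_nail: 110000.0              # titanium
  nu_nail: 0.3
  E_locking: 1000.0             # interlocking interface (screws + bone)
  nu_locking: 0.3
  mixture_exponent: 1.0
rules:
  low_hi: 0.05                  # distortional strain windows
  mid_hi: 0.15
  destroy_hi: 0.30
  compress_thresh: -0.002       # dilatational compression threshold
  shoulder: 0.2                 # relative membership shoulder width
  k_woven: 0.03                 # rates, 1/day
  k_chondro: 0.05
  k_endo: 0.04
  k_remodel: 0.02
  k_resorb: 0.01
  k_destroy: 0.10
  v_rate: 0.3                   # vascular front speed, mm/day
  gamma_angio: 0.06             # angiogenesis strain limit
  v_min: 0.5                    # vascularity gate for ossification
  eta_min: 0.0005               # understimulation floor
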