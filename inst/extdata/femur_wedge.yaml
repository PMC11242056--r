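# Reference configuration: femoral shaft fracture (AO/OTA 32B-like) with a
# laterally based interposed wedge fragment fixed by a 12 mm antegrade
# nail.  The wedge fragment starts devascularized (open reduction).
# Materials and rules fall back to package defaults.
scenario:
  bone_type: femur
  outer_diameter: 26.0
  cortical_thickness: 6.0
  canal_diameter: 13.0
  nail_diameter: 12.0
  segment_length: 46.0
  gap_width: 2.0
  fracture_kind: wedge
  wedge_span: 120.0             # degrees of azimuth
  wedge_height: 6.0             # mm
  wedge_azimuth: -90.0          # lateral
  voxel_size: 1.5
  body_weight: 800.0
  weight_bearing: 1.0
  days: 240
  seed: 1
  peak_multiplier: 2.38
  lock_length: 8.0
  devascularize_fragment: 2
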