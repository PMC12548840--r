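# Default pipeline configuration. All physical constants of the default
# analysis are configured here rather than hard-coded.
actions: [DL, SLDL, TBDL]
seed: 0
noise_sd_mm: 0.5
filters:
  order: 4
  kinematic_cutoff_hz: 10
  force_cutoff_hz: 100
  flexion_lower: L5
  flexion_upper: L1
anthropometry:
  frustum_a1_m: 0.16
  frustum_b1_m: 0.11
  frustum_a2_m: 0.14
  frustum_b2_m: 0.09
  frustum_h_m: 0.45
  density_kg_m3: 1050
  trunk_length_m: 0.45
  com_fraction: 0.45
geometry:
  vertebra_width_mm: 44
  vertebra_depth_mm: 34
  vertebra_height_mm: 27
  cortical_offset_mm: 1
  disc_height_mm: 10
  endplate_thickness_mm: 0.5
  nucleus_radius_frac: 0.4
  annulus_layer_fracs: [0.2, 0.2, 0.2]
  target_edge_mm: 2
  ligament_area_mm2: 30
loads:
  vertical_load_N: 1425
  reference_moment_Nm: 749
thresholds:
  beta: 0.8
  gamma: 1.27
  cortical_damage_MPa: 1000
  trabecular_fatigue_MPa: 3.0
  disc_tolerance_MPa: 40
stats:
  disc: L4-L5
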