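# Fully worked default study configuration. Every block is optional: values
# given here override the package defaults (see default_config()).
materials:
  # example override (commented out): supply the measured glass instead of
  # the shipped synthetic default
  # c40:
  #   density: 5.7
  #   composition: {Cd: 29.99, Te: 34.04, Zn: 4.361, Nb: 12.39, O: 19.21}
phantom:
  breast_dim: [10, 10, 6]
  layer_materials: [gf25, gf50, gf75]
  skin_thickness: 0.2
  gap: 4
  body_dim: [30, 20, 15]
  body_material: soft_tissue
  source_distance: 65
  world_material: air
screens:
  options: [none, lead_acrylic, c40]
  face: [20, 20]
  thickness: 1.2
source:
  energies_keV: [20, 25, 30, 35, 40]
  n_histories: 1.0e6
  seed: 1
transport:
  cutoff_keV: 1
  coherent_enabled: true
  max_interactions: 1000
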