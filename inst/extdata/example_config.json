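{
  "workflow": "soma_sted",
  "seed": 7,
  "output_dir": "mtquant_run",
  "soma_scene": {
    "scene_kind": "soma_sheet",
    "n_microtubules": 200,
    "bundle_fraction": 0.2,
    "fraction_acetylated": 0.45,
    "fraction_tyrosinated": 0.45,
    "fraction_other": 0.10,
    "psf_sigma_axial": 0.1,
    "true_alpha": 0.53,
    "true_beta": 0.45
  },
  "dendrite_scene": {
    "scene_kind": "dendrite",
    "n_microtubules": 159,
    "dendrite_diameter": 1.954,
    "dendrite_length": 4,
    "fraction_acetylated": 0.72,
    "fraction_tyrosinated": 0.26,
    "fraction_other": 0.02,
    "psf_sigma_axial": 0.1,
    "radial_bias": 0.8
  }
}
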