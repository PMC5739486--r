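{
  "grid_n": 64,
  "fov_mm": 200,
  "ellipses": null,
  "background_mu": 0,
  "random": {
    "n_ellipses": [3, 8],
    "body_radius_mm": 90,
    "body_mu": 0.038,
    "delta_range": [-0.012, 0.012],
    "axis_range_mm": [5, 45],
    "n_bones": [2, 3],
    "bone_delta": [0.03, 0.042],
    "bone_axis_mm": [6, 18]
  }
}
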