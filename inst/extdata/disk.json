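{
  "grid_n": 256,
  "fov_mm": 200,
  "ellipses": [
    {
      "cx_mm": 0,
      "cy_mm": 0,
      "a_mm": 50,
      "b_mm": 50,
      "angle_deg": 0,
      "delta_mu": 0.02
    }
  ],
  "background_mu": 0,
  "random": null
}
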