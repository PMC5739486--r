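{
  "grid_n": 256,
  "fov_mm": 200,
  "ellipses": [
    {
      "cx_mm": 0,
      "cy_mm": 0,
      "a_mm": 62.1,
      "b_mm": 82.8,
      "angle_deg": 90,
      "delta_mu": 0.02
    },
    {
      "cx_mm": 0,
      "cy_mm": -1.656,
      "a_mm": 59.616,
      "b_mm": 78.66,
      "angle_deg": 90,
      "delta_mu": -0.016
    },
    {
      "cx_mm": 19.8,
      "cy_mm": 0,
      "a_mm": 9.9,
      "b_mm": 27.9,
      "angle_deg": 72,
      "delta_mu": -0.004
    },
    {
      "cx_mm": -19.8,
      "cy_mm": 0,
      "a_mm": 14.4,
      "b_mm": 36.9,
      "angle_deg": 108,
      "delta_mu": -0.004
    },
    {
      "cx_mm": 0,
      "cy_mm": 31.5,
      "a_mm": 18.9,
      "b_mm": 22.5,
      "angle_deg": 90,
      "delta_mu": 0.002
    },
    {
      "cx_mm": 0,
      "cy_mm": 9,
      "a_mm": 4.14,
      "b_mm": 4.14,
      "angle_deg": 0,
      "delta_mu": 0.002
    },
    {
      "cx_mm": 0,
      "cy_mm": -9,
      "a_mm": 4.14,
      "b_mm": 4.14,
      "angle_deg": 0,
      "delta_mu": 0.002
    },
    {
      "cx_mm": -7.2,
      "cy_mm": -54.45,
      "a_mm": 4.14,
      "b_mm": 2.07,
      "angle_deg": 0,
      "delta_mu": 0.002
    },
    {
      "cx_mm": 0,
      "cy_mm": -54.45,
      "a_mm": 2.07,
      "b_mm": 2.07,
      "angle_deg": 0,
      "delta_mu": 0.002
    },
    {
      "cx_mm": 5.4,
      "cy_mm": -54.45,
      "a_mm": 2.07,
      "b_mm": 4.14,
      "angle_deg": 0,
      "delta_mu": 0.002
    }
  ],
  "background_mu": 0,
  "random": null
}
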