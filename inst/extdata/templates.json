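{
  "version": "1.0",
  "templates": [
    {
      "name": "L",
      "description": "Mean L-cone log10 photopigment absorbance (population mix of ser180/ala180 variants)",
      "order": 8,
      "a0": -42.926358,
      "a": [-2.039680, 57.330821, 8.111103, -21.448345, -3.389620, 3.250756, 0.396600, -0.079354],
      "b": [75.971783, 6.573391, -38.765649, -5.939747, 9.588300, 1.441277, -0.711392, -0.072980],
      "post_scale_kind": "additive_s",
      "post_scale": -0.001655,
      "axis": "log10_nm",
      "lambda_lo": 360,
      "lambda_hi": 850,
      "out_of_range": "error",
      "units": "log_absorbance"
    },
    {
      "name": "M",
      "description": "M-cone log10 photopigment absorbance",
      "order": 8,
      "a0": -210.656885,
      "a": [-0.145807, 305.471058, 6.838622, -118.489020, -3.797355, 19.972851, 0.691341, -0.707069],
      "b": [386.731976, 5.021838, -208.206234, -5.762587, 55.180346, 1.899046, -5.089181, -0.141993],
      "post_scale_kind": "additive_s",
      "post_scale": 0.000589,
      "axis": "log10_nm",
      "lambda_lo": 360,
      "lambda_hi": 850,
      "out_of_range": "error",
      "units": "log_absorbance"
    },
    {
      "name": "S",
      "description": "S-cone log10 photopigment absorbance",
      "order": 8,
      "a0": 207.388095,
      "a": [-6.306562, -315.665060, 19.641474, 121.858468, -8.677406, -20.631872, 1.048302, 0.789878],
      "b": [-393.710048, 19.291754, 214.221157, -15.182074, -56.759638, 3.693488, 5.365662, -0.148036],
      "post_scale_kind": "additive_s",
      "post_scale": 0.000236,
      "axis": "log10_nm",
      "lambda_lo": 360,
      "lambda_hi": 850,
      "out_of_range": "error",
      "units": "log_absorbance"
    },
    {
      "name": "L_ser180_poly",
      "description": "Polymorphic L(ser180) log10 absorbance, fitted for L-cone polymorphic spectra only",
      "order": 8,
      "a0": -42.417609,
      "a": [-2.656792, 56.477063, 9.061442, -20.974610, -3.785039, 3.134495, 0.439302, -0.072988],
      "b": [75.011094, 7.509398, -38.068488, -6.642746, 9.322071, 1.603799, -0.676959, -0.078858],
      "post_scale_kind": "additive_s",
      "post_scale": -0.004264,
      "axis": "log10_nm",
      "lambda_lo": 360,
      "lambda_hi": 850,
      "out_of_range": "error",
      "units": "log_absorbance"
    },
    {
      "name": "L_common",
      "description": "Common shape-invariant LMS template, aligned to L(ser180)",
      "order": 8,
      "a0": -2.125656,
      "a": [5.467793, -0.953011, -3.003999, -1.367085, 0.516505, 0.610042, 0.100928, -0.027880],
      "b": [0.896066, -5.037710, -0.950862, 1.770211, 1.150550, 0.051821, -0.177357, -0.042774],
      "post_scale_kind": "additive_s",
      "post_scale": 0.000705,
      "axis": "log10_nm",
      "lambda_lo": 360,
      "lambda_hi": 850,
      "out_of_range": "error",
      "units": "log_absorbance"
    },
    {
      "name": "macular",
      "description": "Macular pigment optical density spectrum (2-deg standard scaling)",
      "order": 11,
      "a0": 3712.203779,
      "a": [374.181158, -5887.285752, -716.042904, 2882.109266, 468.498070, -817.124090, -144.799646, 115.565280, 18.667820, -5.468375, -0.504396],
      "b": [-7007.698964, -633.047523, 4386.881125, 638.134755, -1653.756739, -286.403898, 340.336483, 59.165083, -30.234454, -4.133506, 0.509417],
      "post_scale_kind": "multiplicative_d",
      "post_scale": 1.005005,
      "axis": "linear_nm",
      "lambda_lo": 375,
      "lambda_hi": 550,
      "out_of_range": "zero",
      "units": "density"
    },
    {
      "name": "lens",
      "description": "Lens pigment optical density spectrum (standard scaling)",
      "order": 9,
      "a0": -313.950863,
      "a": [-70.321682, 471.539586, 127.016822, -188.163808, -68.307849, 33.449826, 13.652409, -1.282577, -0.447784],
      "b": [585.471973, 117.353910, -324.470054, -104.551249, 89.781537, 35.272364, -8.756817, -3.512653, 0.042829],
      "post_scale_kind": "multiplicative_d",
      "post_scale": 1.009187,
      "axis": "linear_nm",
      "lambda_lo": 360,
      "lambda_hi": 660,
      "out_of_range": "zero",
      "units": "density"
    }
  ]
}
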