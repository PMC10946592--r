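{
  "version": "1.0",
  "matrices": [
    {
      "name": "rgb10_to_lms",
      "from": "RGB",
      "to": "LMS",
      "field": "10deg",
      "note": "Stiles-Burch 10-deg RGB CMFs (444/526/645 nm primaries) to cone fundamentals; per-cone scaling absorbed into the B column; S response to R fixed at zero",
      "m": [
        [2.846201, 11.092401, 1.0],
        [0.168926, 8.265895, 1.0],
        [0.0, 0.010600, 1.0]
      ]
    },
    {
      "name": "lms_to_xyz_2deg",
      "from": "LMS",
      "to": "XYZ",
      "field": "2deg",
      "note": "2-deg cone fundamentals to XYZ-like CMFs: y-bar a linear combination of l-bar and m-bar, z-bar a scaled s-bar",
      "m": [
        [1.94735469, -1.41445123, 0.36476327],
        [0.68990272, 0.34832189, 0.0],
        [0.0, 0.0, 1.93485343]
      ]
    },
    {
      "name": "lms_to_xyz_10deg",
      "from": "LMS",
      "to": "XYZ",
      "field": "10deg",
      "note": "10-deg cone fundamentals to XYZ-like CMFs",
      "m": [
        [1.93986443, -1.34664359, 0.43044935],
        [0.69283932, 0.34967567, 0.0],
        [0.0, 0.0, 2.14687945]
      ]
    }
  ]
}
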