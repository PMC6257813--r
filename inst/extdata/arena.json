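{
  "objects": [
    {
      "id": "chair_0",
      "label": "chair",
      "position": [2, 0, 0],
      "radius": 0.5
    },
    {
      "id": "chair_90",
      "label": "chair",
      "position": [1.22464679914735e-16, -2, 0],
      "radius": 0.5
    },
    {
      "id": "chair_180",
      "label": "chair",
      "position": [-2, -2.44929359829471e-16, 0],
      "radius": 0.5
    },
    {
      "id": "chair_270",
      "label": "chair",
      "position": [-3.67394039744206e-16, 2, 0],
      "radius": 0.5
    }
  ],
  "start_zone": {
    "center": [0, 0, 0],
    "radius": 0.5
  }
}
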