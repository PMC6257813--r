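{
  "objects": [
    {
      "id": "trash bin",
      "label": "trash bin",
      "position": [1, 1.73205080756888, 0],
      "radius": 0.5
    },
    {
      "id": "piano",
      "label": "piano",
      "position": [1.73205080756888, 1, 0],
      "radius": 0.5
    },
    {
      "id": "table",
      "label": "table",
      "position": [2, 0, 0],
      "radius": 0.5
    },
    {
      "id": "chair",
      "label": "chair",
      "position": [1.73205080756888, -1, 0],
      "radius": 0.5
    },
    {
      "id": "lamp",
      "label": "lamp",
      "position": [1, -1.73205080756888, 0],
      "radius": 0.5
    }
  ],
  "start_zone": {
    "center": [0, 0, 0],
    "radius": 0.5
  }
}
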