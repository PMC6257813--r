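{
  "objects": [],
  "start_zone": {
    "center": [0, 0, 0],
    "radius": 0.5
  },
  "waypoints": [
    {
      "xyz": [0, 0, 0],
      "turn": "none",
      "stairs": false
    },
    {
      "xyz": [6, 0, 0],
      "turn": "left",
      "stairs": false
    },
    {
      "xyz": [6, 4, 0],
      "turn": "right",
      "stairs": true
    },
    {
      "xyz": [9, 4, 1.5],
      "turn": "none",
      "stairs": true
    },
    {
      "xyz": [12, 4, 3],
      "turn": "left",
      "stairs": false
    },
    {
      "xyz": [12, 6, 3],
      "turn": "left",
      "stairs": false
    },
    {
      "xyz": [10, 6, 3],
      "turn": "right",
      "stairs": false
    },
    {
      "xyz": [10, 8, 3],
      "turn": "right",
      "stairs": false
    },
    {
      "xyz": [23.6917960675006, 8, 3],
      "turn": "none",
      "stairs": false
    }
  ],
  "arrival_radius": 1.2,
  "segment_breaks": [1, 3, 5, 9],
  "segment_labels": ["lobby", "stairwell", "hallway"]
}
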