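{
  "objects": [
    {
      "id": "sofa",
      "label": "sofa",
      "position": [1, 8.5, 0],
      "radius": 0.5
    },
    {
      "id": "coffee table",
      "label": "coffee table",
      "position": [2.5, 7, 0],
      "radius": 0.5
    },
    {
      "id": "tv",
      "label": "tv",
      "position": [1, 5, 0],
      "radius": 0.5
    },
    {
      "id": "bookshelf",
      "label": "bookshelf",
      "position": [1, 2, 0],
      "radius": 0.5
    },
    {
      "id": "piano",
      "label": "piano",
      "position": [3.5, 1, 0],
      "radius": 0.5
    },
    {
      "id": "dining table",
      "label": "dining table",
      "position": [6.5, 1.5, 0],
      "radius": 0.5
    },
    {
      "id": "chair",
      "label": "chair",
      "position": [7, 5, 0],
      "radius": 0.5
    },
    {
      "id": "lamp",
      "label": "lamp",
      "position": [9, 8.8, 0],
      "radius": 0.5
    },
    {
      "id": "plant",
      "label": "plant",
      "position": [9, 1, 0],
      "radius": 0.5
    },
    {
      "id": "fridge",
      "label": "fridge",
      "position": [9.2, 4, 0],
      "radius": 0.5
    },
    {
      "id": "desk",
      "label": "desk",
      "position": [8.5, 6.5, 0],
      "radius": 0.5
    },
    {
      "id": "wardrobe",
      "label": "wardrobe",
      "position": [4, 9, 0],
      "radius": 0.5
    },
    {
      "id": "trash bin",
      "label": "trash bin",
      "position": [6, 9, 0],
      "radius": 0.5
    },
    {
      "id": "rug",
      "label": "rug",
      "position": [5, 3.2, 0],
      "radius": 0.5
    },
    {
      "id": "stool",
      "label": "stool",
      "position": [3, 4, 0],
      "radius": 0.5
    },
    {
      "id": "key",
      "label": "key",
      "position": [6.5, 6.8, 0],
      "radius": 0.15
    }
  ],
  "start_zone": {
    "center": [5, 5, 0],
    "radius": 0.5
  },
  "grid": {
    "cell_size": 0.1,
    "rows": 100,
    "cols": 100,
    "origin": [0, 0],
    "blocked": []
  }
}
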