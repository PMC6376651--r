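{
  "center": "d1",
  "nodes": [
    {
      "id": "d1",
      "rarity": "RD",
      "center": true
    },
    {
      "id": "d2",
      "rarity": "CD",
      "center": false
    },
    {
      "id": "d3",
      "rarity": "RD",
      "center": false
    }
  ],
  "links": [
    {
      "source": "d1",
      "target": "d2",
      "weight": 0.333333333333333
    },
    {
      "source": "d1",
      "target": "d3",
      "weight": 1
    },
    {
      "source": "d2",
      "target": "d3",
      "weight": 0.333333333333333
    }
  ]
}
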