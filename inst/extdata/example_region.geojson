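{
  "type": "Feature",
  "properties": {"name": "synthetic analysis region", "crs": "local planar meters"},
  "geometry": {
    "type": "Polygon",
    "coordinates": [[[57, 0], [943, 0], [943, 50], [57, 50], [57, 0]]]
  }
}
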