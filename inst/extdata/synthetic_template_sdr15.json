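{
  "template_id": "synthetic_template",
  "positions": [167, 190, 234, 235, 236, 239, 278, 299, 301, 322, 324, 330, 331, 335, 400],
  "provenance": ["distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "manual", "manual", "manual", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived"],
  "cutoff": 6
}
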