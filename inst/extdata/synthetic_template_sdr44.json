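{
  "template_id": "synthetic_template",
  "positions": [167, 190, 205, 208, 211, 215, 222, 230, 232, 234, 235, 236, 238, 239, 240, 243, 250, 255, 260, 265, 270, 275, 278, 280, 285, 290, 298, 299, 300, 301, 305, 310, 315, 320, 322, 324, 326, 330, 331, 332, 335, 345, 360, 400],
  "provenance": ["distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived", "distance-derived"],
  "cutoff": 10
}
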