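{
  "topology_id": "facemesh468",
  "K": 468,
  "index_base": 0,
  "note": "Approximate region grouping for the canonical 468-landmark face-mesh topology. head_rigid collects quasi-rigid landmarks (nose bridge, forehead midline, temples, face-oval anchors); the periocular sets pool eye contour and eyebrow landmarks; perioral pools outer and inner lip contours. Remaining indices form the 'other' region at load time.",
  "regions": {
    "head_rigid": [1, 2, 4, 5, 6, 8, 9, 10, 98, 109, 127, 151, 162, 168, 195, 197, 234, 327, 338, 356, 389, 454],
    "left_periocular": [249, 263, 276, 282, 283, 285, 293, 295, 296, 300, 334, 336, 362, 373, 374, 380, 381, 382, 384, 385, 386, 387, 388, 390, 398, 466],
    "right_periocular": [7, 33, 46, 52, 53, 55, 63, 65, 66, 70, 105, 107, 133, 144, 145, 153, 154, 155, 157, 158, 159, 160, 161, 163, 173, 246],
    "perioral": [0, 13, 14, 17, 37, 39, 40, 61, 78, 80, 81, 82, 84, 87, 88, 91, 95, 146, 178, 181, 185, 191, 267, 269, 270, 291, 308, 310, 311, 312, 314, 317, 318, 321, 324, 375, 402, 405, 409, 415]
  }
}
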