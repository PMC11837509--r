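[
  {"pathway_id": "P1", "ec_list": ["a1", "a2"]},
  {"pathway_id": "P2", "ec_list": ["b1"], "variant_class": "V1"},
  {"pathway_id": "P3", "ec_list": ["c1", "c2"]},
  {"pathway_id": "P4", "ec_list": ["d1"], "variant_class": "V1"},
  {"pathway_id": "P5", "ec_list": ["e1", "e2"]}
]
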