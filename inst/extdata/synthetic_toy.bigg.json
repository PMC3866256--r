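{
  "id": "synthetic_toy",
  "metabolites": [
    {"id": "A", "compartment": "c", "name": "metabolite A"},
    {"id": "B", "compartment": "c", "name": "metabolite B"},
    {"id": "C", "compartment": "c", "name": "metabolite C"}
  ],
  "reactions": [
    {"id": "EX_in", "metabolites": {"A": 1}, "lower_bound": 0,
     "upper_bound": 5, "gene_reaction_rule": ""},
    {"id": "R_AB", "metabolites": {"A": -1, "B": 1}, "lower_bound": 0,
     "upper_bound": 1000, "gene_reaction_rule": "(g1 and g2) or g3"},
    {"id": "R_BC", "metabolites": {"B": -1, "C": 1}, "lower_bound": -1000,
     "upper_bound": 1000, "gene_reaction_rule": ""},
    {"id": "EX_out", "metabolites": {"C": -1}, "lower_bound": 0,
     "upper_bound": 1000, "gene_reaction_rule": "",
     "objective_coefficient": 1}
  ],
  "genes": [
    {"id": "g1"}, {"id": "g2"}, {"id": "g3"}
  ]
}
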