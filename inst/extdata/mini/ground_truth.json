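{
  "comment": "synthetic hand-built fixture; labels are 1 iff max C[m,g] >= tau over the protein's motifs m and the drug's fragments g",
  "motif_pool": ["ACDEFG", "KLMNPQ"],
  "fragment_vocab": ["CCC", "c1ccccc1", "C(=O)O"],
  "C": [[0.9, 0.2, 0.4], [0.1, 0.3, 0.8]],
  "tau": 0.5,
  "protein_motifs": {"P1": [1], "P2": [2], "P3": [1]},
  "drug_fragments": {"D1": [1, 2], "D2": [3, 1], "D3": [2, 3]}
}
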