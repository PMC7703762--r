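{
  "comment": "Cellular motif sets over the 2-5-node graphlet catalogue (ids G0..G29, density-ordered; G0..G8 follow the standard literature numbering). Membership is a SYNTHETIC transcription: the published mauve/blue figure partition is not machine-readable, so the sets below are constructed to the published cardinalities (29 motifs over 26 distinct graphlets, with G8, G23 and G26 each realizing two motifs; a 17-motif default subset) using a structural rule: the 5-clique (G29), the 5-clique minus one edge (G28), the densest remaining 8-edge graph (G27) and the 5-star (G11, not realizable as an induced contact pattern around a packed cell whose neighbors form a ring) are excluded.",
  "synthetic_transcription": true,
  "sets": [
    {
      "name": "full-29",
      "description": "All cellular motifs admissible in a planar packed tissue: 26 graphlets, 29 motifs (G8, G23, G26 doubled).",
      "graphlets": [
        {"id": "G0", "multiplicity": 1},
        {"id": "G1", "multiplicity": 1},
        {"id": "G2", "multiplicity": 1},
        {"id": "G3", "multiplicity": 1},
        {"id": "G4", "multiplicity": 1},
        {"id": "G5", "multiplicity": 1},
        {"id": "G6", "multiplicity": 1},
        {"id": "G7", "multiplicity": 1},
        {"id": "G8", "multiplicity": 2},
        {"id": "G9", "multiplicity": 1},
        {"id": "G10", "multiplicity": 1},
        {"id": "G12", "multiplicity": 1},
        {"id": "G13", "multiplicity": 1},
        {"id": "G14", "multiplicity": 1},
        {"id": "G15", "multiplicity": 1},
        {"id": "G16", "multiplicity": 1},
        {"id": "G17", "multiplicity": 1},
        {"id": "G18", "multiplicity": 1},
        {"id": "G19", "multiplicity": 1},
        {"id": "G20", "multiplicity": 1},
        {"id": "G21", "multiplicity": 1},
        {"id": "G22", "multiplicity": 1},
        {"id": "G23", "multiplicity": 2},
        {"id": "G24", "multiplicity": 1},
        {"id": "G25", "multiplicity": 1},
        {"id": "G26", "multiplicity": 2}
      ]
    },
    {
      "name": "motifs-17",
      "description": "Default reduced set: the 17 sparsest motifs of full-29 (through the 5-edge graphlets on 5 nodes; G8 doubled).",
      "graphlets": [
        {"id": "G0", "multiplicity": 1},
        {"id": "G1", "multiplicity": 1},
        {"id": "G2", "multiplicity": 1},
        {"id": "G3", "multiplicity": 1},
        {"id": "G4", "multiplicity": 1},
        {"id": "G5", "multiplicity": 1},
        {"id": "G6", "multiplicity": 1},
        {"id": "G7", "multiplicity": 1},
        {"id": "G8", "multiplicity": 2},
        {"id": "G9", "multiplicity": 1},
        {"id": "G10", "multiplicity": 1},
        {"id": "G12", "multiplicity": 1},
        {"id": "G13", "multiplicity": 1},
        {"id": "G14", "multiplicity": 1},
        {"id": "G15", "multiplicity": 1},
        {"id": "G16", "multiplicity": 1}
      ]
    }
  ]
}
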