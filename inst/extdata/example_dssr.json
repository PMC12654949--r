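{
  "num_pairs": 3,
  "pairs": [
    {"nt1": "A.G1",  "nt2": "A.C20", "bp": "G-C", "name": "WC",        "LW": "cWW", "DSSR": "cW-W"},
    {"nt1": "A.G3",  "nt2": "A.U18", "bp": "G-U", "name": "Wobble",    "LW": "cWW", "DSSR": "cW-W"},
    {"nt1": "A.A4",  "nt2": "A.U17", "bp": "A-U", "name": "Hoogsteen", "LW": "tHW", "DSSR": "tH-W"}
  ]
}
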