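PDB data file name: synthetic_example
BASE_PAIR:
     1_20, A:     1 G-C    20 A: +/+ cis         XIX
     2_19, A:     2 A-U    19 A: +/+ cis         XX
     3_18, A:     3 G-U    18 A: W/W cis         XXVIII
     4_17, A:     4 A-G    17 A: H/W tran        !1H(b_b)
     5_6, A:     5 G-A     6 A:      stacked
END_base-pair
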