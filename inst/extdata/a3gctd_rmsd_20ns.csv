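run,xtal_vs_xtal,xtal_vs_nmr,xtal_ligand_h2o,nmr_vs_nmr,nmr_vs_xtal,nmr_ligand_h2o
1,1.85,3.59,0.43,2.21,4.02,0.30
2,1.96,4.09,0.32,3.75,4.13,0.52
3,2.23,4.29,0.34,1.86,3.87,0.22
4,2.13,4.34,0.50,2.28,4.05,0.49
5,1.80,3.85,0.46,2.62,4.56,0.25
6,2.48,3.78,0.27,2.76,4.52,0.33
7,2.77,3.64,0.46,2.76,3.90,0.32
8,1.82,3.82,0.30,2.29,4.72,0.31
9,1.58,4.13,0.57,3.27,3.84,0.32
10,1.82,4.18,0.58,2.59,4.00,0.31
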