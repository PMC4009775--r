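run,xtal_vs_xtal,xtal_vs_nmr,xtal_ligand_h2o,nmr_vs_nmr,nmr_vs_xtal,nmr_ligand_h2o
1,2.22,3.36,0.43,2.21,4.02,0.30
2,1.63,3.75,0.32,3.75,4.13,0.33
3,1.93,4.31,0.34,1.86,3.87,0.23
4,2.11,3.91,0.49,2.47,4.41,0.42
5,1.70,4.07,0.46,2.62,4.56,0.46
6,1.72,3.96,0.27,2.76,4.52,0.44
7,2.38,3.41,0.46,2.76,3.90,0.42
8,2.27,3.56,0.29,2.29,4.72,0.28
9,1.88,4.10,0.57,3.27,3.84,0.33
10,1.97,3.80,0.58,2.59,4.00,0.28
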