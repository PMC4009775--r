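arginine,nmr_vs_nmr,nmr_vs_xtal,xtal_vs_xtal,xtal_vs_nmr
Arg213,3.95,8.20,3.38,8.42
Arg215,4.24,8.64,2.60,8.35
Arg320,2.29,2.24,1.53,1.95
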