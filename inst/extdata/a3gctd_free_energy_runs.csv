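form,run,g2,ts_printed,g1
crystal,1,-6043.13,-6702.60,-12745.74
crystal,2,-6036.39,-6736.90,-12773.30
crystal,3,-6044.5,-6847.83,-12892.33
crystal,4,-6047.56,-6750.79,-12798.36
crystal,5,-6024.11,-6719.73,-12743.84
crystal,6,-6065.13,-6664.80,-12729.94
crystal,7,-6034.97,-6781.37,-12816.35
crystal,8,-6040.02,-6734.99,-12775.01
crystal,9,-6026.65,-6828.27,-12854.92
crystal,10,-6036.85,-6849.60,-12886.46
nmr,1,-5884.37,-7027.53,-12911.90
nmr,2,-5944.13,-7121.26,-13065.39
nmr,3,-5923.86,-6868.51,-12792.37
nmr,4,-5939.21,-7080.32,-13019.53
nmr,5,-5936.12,-6916.54,-12852.66
nmr,6,-5895.72,-6944.52,-12840.24
nmr,7,-5935.67,-6947.93,-12883.60
nmr,8,-5915.02,-6966.65,-12881.67
nmr,9,-5941.27,-6922.34,-12863.61
nmr,10,-5900.79,-6926.11,-12826.90
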