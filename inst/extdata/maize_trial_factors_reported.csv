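regime,factor,eigenvalue,variance_pct,cumulative_pct
optimal,FA1,4.54,37.83,37.83
optimal,FA2,2.51,20.93,58.77
optimal,FA3,1.21,10.10,68.86
drought,FA1,3.47,28.90,28.90
drought,FA2,2.21,18.38,47.28
drought,FA3,1.43,11.94,59.22
drought,FA4,1.25,10.39,69.61
waterlogging,FA1,4.16,34.64,34.64
waterlogging,FA2,2.40,20.02,54.66
waterlogging,FA3,1.47,12.26,66.92
waterlogging,FA4,1.14,9.52,76.43
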