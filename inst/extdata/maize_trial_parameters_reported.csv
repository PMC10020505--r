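regime,trait,h2mg,accuracy
optimal,D50A,0.93,0.96
optimal,D50S,0.92,0.96
optimal,ASI,0.16,0.40
optimal,PH,0.61,0.78
optimal,EH,0.86,0.93
optimal,SPAD,0.33,0.57
optimal,EL,0.62,0.78
optimal,EG,0.63,0.79
optimal,KRE,0.73,0.85
optimal,KNR,0.40,0.63
optimal,TW,0.61,0.78
optimal,GY,0.75,0.86
drought,D50A,0.54,0.73
drought,D50S,0.29,0.53
drought,ASI,0.38,0.62
drought,PH,0.78,0.88
drought,EH,0.68,0.83
drought,SPAD,0.51,0.31
drought,EL,0.38,0.62
drought,EG,0.30,0.53
drought,KRE,0.61,0.78
drought,KNR,0.42,0.65
drought,TW,0.49,0.70
drought,GY,0.59,0.76
waterlogging,D50A,0.77,0.88
waterlogging,D50S,0.55,0.74
waterlogging,ASI,0.43,0.65
waterlogging,PH,0.81,0.89
waterlogging,EH,0.71,0.84
waterlogging,SPAD,0.86,0.93
waterlogging,EL,0.82,0.91
waterlogging,EG,0.81,0.90
waterlogging,KRE,0.74,0.86
waterlogging,KNR,0.78,0.89
waterlogging,TW,0.71,0.84
waterlogging,GY,0.83,0.91
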