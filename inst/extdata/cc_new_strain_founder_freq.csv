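strain,A/J,C57BL/6J,129S1/SvImJ,NOD/ShiLtJ,NZO/HlLtJ,CAST/EiJ,PWK/PhJ,WSB/EiJ
CC078/TauUnc,0.176,0.166,0.142,0.113,0.046,0.098,0.136,0.123
CC079/TauUnc,0.199,0.147,0.130,0.086,0.109,0.157,0.135,0.038
CC080/TauUnc,0.163,0.223,0.151,0.059,0.182,0.055,0.027,0.140
CC081/Unc,0.089,0.148,0.181,0.154,0.153,0.071,0.101,0.096
CC082/Unc,0.148,0.101,0.062,0.107,0.150,0.177,0.099,0.149
CC083/Unc,0.177,0.166,0.142,0.110,0.046,0.098,0.136,0.123
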