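strain,mrca_het_pct,sequenced_het_pct,minimuga_het_pct
CC078/TauUnc,14.29996,1.7,5.52
CC079/TauUnc,6.766071,4.5,8.62
CC080/TauUnc,22.18861,3.77,17.11
CC081/Unc,21.91887,3.7,18.81
CC082/Unc,22.76935,5,18.84
CC083/Unc,31.48258,15.4,28.87
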