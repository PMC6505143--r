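strain,chromosome,kmer_start,kmer_end,resolved_start,resolved_end,size_kb,spanning_reads,haplotype
CC079/TauUnc,8,102931561,102947356,102931583,102947323,15.795,NA,129S1/SvImJ
CC079/TauUnc,X,11600371,11620171,11600372,11620112,19.8,11,PWK/PhJ
CC079/TauUnc,2,129264616,129265201,129264705,129265185,0.585,37,PWK/PhJ
CC081/Unc,10,56858446,56862406,56858470,56862407,3.96,40,C57BL/6J
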