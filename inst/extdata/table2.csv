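reason,m05_12,m13_18,m19_24,m25_36
no clinical improvement,18,11,8,21
medical issue,3,1,2,0
improved efficacy,0,0,0,24
schooling,3,3,0,5
side effects,2,1,1,2
COVID-19,9,7,3,1
personal issue,0,3,0,4
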