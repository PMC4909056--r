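provenance,bai_cm2_yr,abi_kg_yr
SK,33.36,3.6
UA,23.20,4.0
ES,4.34,NA
SL,5.68,1.02
SE,NA,1.69
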