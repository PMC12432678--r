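serum_id,cell_id,cell_genotype,compartment,mcs,printed
S2-AE2,FX2-1,B*35:01+B*15:16,T,45,NEG
S2-AE2,FX2-2,B*35:08+B*15:17,T,334,POS
B,FX2-1,B*35:01+B*15:16,T,265,POS
B,FX2-2,B*35:08+B*15:17,T,253,POS
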