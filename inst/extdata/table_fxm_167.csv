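serum_id,cell_id,cell_genotype,compartment,mcs,printed
S1-AE1,FX1-1,B*50:01+B*50:01,T,0,NEG
S1-AE1,FX1-2,B*35:01+B*50:02,T,104,POS
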