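broad,split,associated,allele,untreated,ae1,score,pos167
A1,,,A*01:01,7856,4368,POS,G
A1,,,A*01:02,5936,3928,POS,G
A3,,A-0301,A*03:01,30531,31,NEG,W
A3,,A-0301,A*03:02,27724,0,NEG,W
A9,A23,A-2301,A*23:01,31664,3603,POS,G
A9,A24,A-2402,A*24:02,26807,3015,POS,G
A9,A24,A2403,A*24:03,31744,0,NEG,W
A36,,,A*36:01,238,15,NEG,W
A80,,,A*80:01,3413,1147,POS,G
B12,B44,B-4402,B*44:02,29814,4801,POS,S
B12,B44,B-4402,B*44:03,30712,4941,POS,S
B12,B45,,B*45:01,29490,4945,POS,S
B12,B45,,B*50:02,27118,4486,POS,S
B21,B49,,B*49:01,30920,36,NEG,W
B21,B50,,B*50:01,28965,71,NEG,W
B21,B50,B4005,B*40:05,31437,52,NEG,W
B15,B76,,B*15:12,28513,5684,POS,G
B15,B76,,B*15:14,NA,NA,NA,S
B82,,,B*82:01,30569,4462,POS,S
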