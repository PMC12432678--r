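subject_id,allele
S1,A*02:17
S1,A*11:01
S1,B*18:01
S1,B*35:01
S1,C*07:01
S1,C*04:01
S1,DRB1*09:01
S1,DRB1*15:02
S1,DRB5*01:02
S1,DRB4*01:03
S1,DQA1*03:01
S1,DQA1*01:03
S1,DQB1*03:02
S1,DQB1*06:01
S1,DPA1*02:01
S1,DPA1*01:03
S1,DPB1*10:01
S1,DPB1*02:01
S2,A*02:01
S2,A*29:02
S2,B*58:01
S2,B*56:01
S2,C*07:18
S2,C*01:02
S2,DRB1*08:04
S2,DRB1*01:01
S2,DQA1*01:01
S2,DQA1*04:01
S2,DQB1*04:02
S2,DQB1*05:01
S2,DPA1*01:03
S2,DPB1*03:01
S2,DPB1*04:02
S3,A*02:01
S3,B*44:02
S3,B*27:05
S3,C*05:01
S3,C*01:02
S3,DRB1*14:54
S3,DRB1*01:01
S3,DRB3*02:02
S3,DQA1*01:04
S3,DQA1*01:01
S3,DQB1*05:03
S3,DQB1*05:01
S3,DPA1*01:03
S3,DPA1*02:01
S3,DPB1*04:02
S3,DPB1*14:01
AE1,A*01:01
AE2,A*02:01
AE2,B*35:17
AE2,B*35:12
AE2,C*04:01
AE3,B*57:01
FX1-1,A*02:05
FX1-1,A*33:03
FX1-1,B*50:01
FX1-1,C*06:02
FX1-2,A*02:05
FX1-2,A*02:01
FX1-2,B*50:02
FX1-2,B*35:01
FX1-2,C*15:09
FX1-2,C*06:02
FX2-1,A*33:03
FX2-1,A*02:02
FX2-1,B*35:01
FX2-1,B*15:16
FX2-1,C*04:01
FX2-1,C*14:02
FX2-2,A*02:01
FX2-2,A*02:11
FX2-2,B*35:08
FX2-2,B*15:17
FX2-2,C*04:01
FX2-2,C*07:01
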