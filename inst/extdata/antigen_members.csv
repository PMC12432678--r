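allele,antigen,pos103,pos109,pos96
B*07:02,B-0702,V,L,
B*07:12,B-0702,L,L,
B*44:02,B-4402,V,L,
B*44:03,B-4402,V,L,
B*44:10,B-4402,L,L,
B*15:01,B-1501,V,L,
B*15:04,B-1501,V,L,
B*15:20,B-1501,L,L,
B*55:01,B-5501,L,L,
B*55:02,B-5501,L,L,
B*55:04,B-5501,V,L,
B*56:01,B-5601,L,L,
B*56:03,B-5601,V,L,
B*27:04,B-2705,V,L,
B*27:05,B-2705,V,L,
B*27:14,B-2705,L,L,
B*35:01,B-3501,L,L,
B*35:03,B-3501,L,L,
B*35:08,B-3501,L,L,
B*35:02,B-3501,L,F,
B*35:12,B-3501,V,L,
B*35:17,B-3501,V,L,
B*35:10,B-3510,L,L,
B*35:16,B-3510,V,L,
B*35:15,B-3515,L,L,
B*35:31,B-3515,V,L,
B*40:02,B-4002,V,L,
B*40:03,B-4002,V,L,
B*40:04,B-4002,L,L,
B*15:03,B-1503,V,L,
B*48:02,B-1503,L,L,
B*78:01,B-7801,V,L,
B*35:21,B-7801,L,L,
DPB1*04:01,DP-401,,,R
DPB1*15:01,DP-401,,,K
DPB1*06:01,DP-06,,,K
DPB1*17:01,DP-06,,,R
DPB1*04:02,DP-0402,,,R
DPB1*18:01,DP-0402,,,K
DPB1*13:01,DP-13,,,K
DPB1*30:01,DP-13,,,R
DPB1*01:01,DP-01,,,K
DPB1*31:01,DP-01,,,R
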