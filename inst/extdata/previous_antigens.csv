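antigen,prototype,split,broad
B-0702,B*07:02,,B7
B-4402,B*44:02,B44,B12
B-1501,B*15:01,B62,B15
B-5501,B*55:01,B55,B22
B-5601,B*56:01,B56,B22
B-2705,B*27:05,,B27
B-3501,B*35:01,,B35
B-3510,B*35:10,,
B-3515,B*35:15,,
B-4002,B*40:02,B61,B40
B-1503,B*15:03,B72,B70
B-7801,B*78:01,,B78
DP-401,DPB1*04:01,,
DP-06,DPB1*06:01,,
DP-0402,DPB1*04:02,,
DP-13,DPB1*13:01,,
DP-01,DPB1*01:01,,
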