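id,proposed,dep1,previous,dep2,split,broad
1,B-0712,103L,B-0702,103V,,B7
2,B-4410,103L,B-4402,103V,B44,B12
3,B-1520,103L,B-1501,103V,B62,B15
4,B-5504,103V,B-5501,103L,B55,B22
5,B-5603,103V,B-5601,103L,B56,B22
6,B-2714,103L,B-2705,103V,,B27
7,B-3512,103V,B-3501,103L,,B35
8,B-3516,103V,B-3510,103L,,
9,B-3531,103V,B-3515,103L,,
10,B-4004,103L,B-4002,103V,B61,B40
11,B-4802,103L,B-1503,103V,B72,B70
12,B-3521,103L,B-7801,103V,,B78
13,B-3502,109F,B-3501,109L,,B35
14,DP-15,96K,DP-401,96R,,
15,DP-17,96R,DP-06,96K,,
16,DP-18,96K,DP-0402,96R,,
17,DP-30,96R,DP-13,96K,,
18,DP-31,96R,DP-01,96K,,
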