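broad,split,associated,allele,untreated,ae2,ae3,pos103,pos109,self,label
A2,,A-0201,A*02:01,0,396,6,V,F,1,NEG
A9,A23,A-2301,A*23:01,32914,0,0,V,F,0,NEG
A9,A24,A-2402,A*24:02,33320,0,0,V,F,0,NEG
A9,A24,A2403,A*24:03,34655,0,0,V,F,0,NEG
A19,A29,A-2902,A*29:02,73,0,0,V,F,1,NEG
A19,A32,A-3201,A*32:01,20487,19750,12119,V,L,0,POS
A19,A74,,A*74:01,12951,19410,11633,V,L,0,POS
B7,,,B*07:02,31339,7054,2738,V,L,0,POS
B7,,,B*07:14,31556,7182,2774,V,L,0,POS
B8,,,B*08:01,10431,7505,4057,V,L,0,POS
B13,,,B*13:01,23010,3796,628,L,L,0,NEG
B13,,,B*13:02,27701,4770,820,L,L,0,NEG
B14,B64,,B*14:01,18889,16808,10982,V,L,0,POS
B14,B65,,B*14:02,16066,15669,9729,V,L,0,POS
B15,B62,B-1501,B*15:01,21152,19126,10799,V,L,0,POS
B15,B62,B-1501,B*15:04,17488,17671,9877,V,L,0,POS
B15,B62,B-1501,B*15:06,19051,17816,10183,V,L,0,POS
B15,B62,B-1501,B*15:07,20242,18520,10720,V,L,0,POS
B15,B62,B-1501,B*15:27,19786,18267,10147,V,L,0,POS
B15,B62,B-1520,B*15:20,7335,3803,1076,L,L,0,NEG
B15,B62,B-1524,B*15:24,16378,16155,9317,V,L,0,POS
B15,B63,B-1516,B*15:16,3123,0,954,L,L,0,NEG
B15,B63,B-1517,B*15:17,19391,18475,11696,V,L,0,POS
B15,B75,B-1502,B*15:02,18578,17597,10080,V,L,0,POS
B15,B75,B-1502,B*15:21,18755,17368,10185,V,L,0,POS
B15,B75,B-1511,B*15:11,15397,14942,9203,V,L,0,POS
B15,B76,,B*15:12,26366,16772,8859,V,L,0,POS
B15,B77,,B*15:13,14707,14036,8477,V,L,0,POS
B15/B70,B71,B-1510,B*15:10,19611,18090,10932,V,L,0,POS
B15/B70,B71,B-1510,B*15:18,19340,18077,10803,V,L,0,POS
B15/B70,B72,B-1503,B*15:03,19776,18435,10757,V,L,0,POS
B15/B70,B72,B-4802,B*48:02,1756,1316,3,L,L,0,NEG
B18,,,B*18:01,20142,19233,12415,V,L,0,POS
B27,,B-2705,B*27:04,30655,18563,11048,V,L,0,POS
B27,,B-2705,B*27:05,29844,19153,11585,V,L,0,POS
B27,,B-2705,B*27:06,29375,18139,11140,V,L,0,POS
B27,,B2708,B*27:08,30617,19447,11726,V,L,0,POS
B35,,B-3501,B*35:01,1108,965,4,L,L,0,NEG
B35,,B-3501,B*35:03,718,660,0,L,L,0,NEG
B35,,B-3501,B*35:08,720,755,0,L,L,0,NEG
B35,,B-3502,B*35:02,662,590,0,L,F,0,NEG
B35,,B-3512,B*35:12,17358,17805,10458,V,L,0,POS
B37,,B-3701,B*37:01,18669,18742,11300,V,L,0,POS
B16,B38,B-3801,B*38:01,16825,17716,11027,V,L,0,POS
B16,B38,B-3801,B*38:02,19502,19553,11593,V,L,0,POS
B16,B39,B3901,B*39:01,19218,18217,11584,V,L,0,POS
B16,B39,B3901,B*39:04,18247,17587,11189,V,L,0,POS
B16,B39,B3901,B*39:05,18898,18646,11509,V,L,0,POS
B16,B39,B3901,B*39:06,16425,16454,9940,V,L,0,POS
B16,B39,B3902,B*39:02,20308,19544,11775,V,L,0,POS
B16,B39,B3902,B*39:13,21171,20528,12325,V,L,0,POS
B40,B60,B-4001,B*40:01,27892,7626,2709,V,L,0,POS
B40,B61,B-4002,B*40:02,27481,18082,11213,V,L,0,POS
B40,B61,B-4002,B*40:03,27448,18051,10474,V,L,0,POS
B40,B61,B-4002,B*40:06,26079,16977,10015,V,L,0,POS
B40,B61,B-4004,B*40:04,27101,2317,0,L,L,0,NEG
B41,,,B*41:01,7854,5152,1641,V,L,0,POS
B41,,,B*41:02,9031,5806,2139,V,L,0,POS
B42,,,B*42:01,10290,4813,2280,V,L,0,POS
B42,,,B*42:02,9267,4618,2022,V,L,0,POS
B12,B44,B-4402,B*44:02,18719,16669,9939,V,L,0,POS
B12,B44,B-4402,B*44:03,19985,17594,10295,V,L,0,POS
B12,B45,,B*45:01,13012,1633,0,L,L,0,NEG
B12,B45,,B*50:02,12937,1596,0,L,L,0,NEG
B46,,,B*46:01,17987,18791,11849,V,L,0,POS
B47,,B-4701,B*47:01,20863,13706,8613,V,L,0,POS
B48,,B-4801,B*48:01,27099,8064,3912,V,L,0,POS
B21,B49,,B*49:01,3304,1788,0,L,L,0,NEG
B21,B50,,B*50:01,2230,1376,0,L,L,0,NEG
B21,B50,B4005,B*40:05,16702,17517,10552,V,L,0,POS
B5,B51,B-5101,B*51:01,15408,15819,9492,V,L,0,POS
B5,B51,B5102,B*51:02,15985,16968,10114,V,L,0,POS
B5,B52,,B*52:01,13260,14526,8497,V,L,0,POS
B53,,,B*53:01,727,694,0,L,L,0,NEG
B22,B54,,B*54:01,17,0,0,L,L,0,NEG
B22,B55,B-5501,B*55:01,1298,0,0,L,L,0,NEG
B22,B55,B-5501,B*55:02,38,0,0,L,L,0,NEG
B22,B55,B-5504,B*55:04,17286,17427,10456,V,L,0,POS
B22,B56,B-5601,B*56:01,0,0,0,L,L,1,NEG
B22,B56,B-5603,B*56:03,16789,16864,9760,V,L,0,POS
B17,B57,,B*57:01,20174,19483,12609,V,L,0,POS
B17,B57,,B*57:03,18562,18182,11668,V,L,0,POS
B17,B58,,B*58:01,0,0,0,L,L,1,NEG
B59,,,B*59:01,81,0,0,L,L,0,NEG
B67,,B-6701,B*67:01,21905,20313,12337,V,L,0,POS
B73,,,B*73:01,28662,307,0,M,L,0,NEG
B78,,B-7801,B*78:01,15441,16051,9556,V,L,0,POS
B81,,,B*81:01,29686,7013,2980,V,L,0,POS
B82,,,B*82:01,12417,0,0,L,L,0,NEG
Cw1,,,C*01:02,38,0,200,L,L,1,NEG
Cw3,Cw9,,C*03:03,22001,16915,9561,V,L,0,POS
Cw3,Cw10,C-0304,C*03:02,19755,15003,8683,V,L,0,POS
Cw3,Cw10,C-0304,C*03:04,20997,15620,8834,V,L,0,POS
Cw7,,C-0701,C*07:01,162,0,0,L,L,1,NEG
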