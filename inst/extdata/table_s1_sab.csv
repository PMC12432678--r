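broad,split,associated,allele,untreated,ae2,ae3,pos69,pos82,pos83,pos103,pos109,self
A2,,,A*02:01,118,100,49,,,,V,F,1
A9,A23,A-2301,A*23:01,33496,0,22029,,L,R,V,F,0
A9,A24,A-2402,A*24:02,29077,0,17820,,L,R,V,F,0
A9,A24,A2403,A*24:03,32649,0,22143,,L,R,V,F,0
A10,A25,,A*25:01,33544,0,19147,,L,R,V,F,0
A11,,,A*11:01,337,17,92,,,,V,F,1
A19,A32,A-3201,A*32:01,33504,537,23851,,L,R,V,L,0
A19,A74,,A*74:01,21716,576,2561,,,,V,L,0
B7,,,B*07:02,30302,18093,27685,A,,,V,L,0
B7,,,B*07:14,30652,16069,26885,A,,,V,L,0
B8,,,B*08:01,35397,17366,15722,,,,V,L,0
B13,,,B*13:01,29090,3287,8806,,L,R,L,L,0
B13,,,B*13:02,33741,5443,12592,,L,R,L,L,0
B14,B64,,B*14:01,16018,298,813,,,,V,L,0
B14,B65,,B*14:02,14448,578,424,,,,V,L,0
B15,B62,B-1501,B*15:01,32521,1051,8667,,,,V,L,0
B15,B62,B-1501,B*15:04,28283,1979,7758,,,,V,L,0
B15,B62,B-1501,B*15:06,27969,77,7344,,,,V,L,0
B15,B62,B-1501,B*15:07,30670,2971,8479,,,,V,L,0
B15,B62,B-1501,B*15:27,30562,354,7187,,,,V,L,0
B15,B62,B-1520,B*15:20,26767,18,6670,,,,L,L,0
B15,B62,B-1524,B*15:24,25333,773,8543,,L,R,V,L,0
B15,B63,B-1516,B*15:16,31940,0,22916,A,L,R,L,L,0
B15,B63,B-1517,B*15:17,34030,732,23497,A,L,R,V,L,0
B15,B75,B-1502,B*15:02,16291,0,6822,,,,V,L,0
B15,B75,B-1502,B*15:21,16739,0,6638,,,,V,L,0
B15,B75,B-1511,B*15:11,6742,70,1961,,,,V,L,0
B15,B76,,B*15:12,31142,507,6796,,,,V,L,0
B15,B77,,B*15:13,14886,0,6916,,L,R,V,L,0
B15/B70,B71,B-1510,B*15:10,28330,1803,801,,,,V,L,0
B15/B70,B71,B-1510,B*15:18,25291,394,246,,,,V,L,0
B15/B70,B72,B-1503,B*15:03,27773,1773,4752,,,,V,L,0
B15/B70,B72,B-4802,B*48:02,20489,0,950,,,,L,L,0
B18,,,B*18:01,3,0,0,,,,V,L,1
B27,,B-2705,B*27:04,32985,7153,24698,A,L,R,V,L,0
B27,,B-2705,B*27:05,32284,6994,24873,A,L,R,V,L,0
B27,,B-2705,B*27:06,33498,7220,24499,A,L,R,V,L,0
B27,,B2708,B*27:08,32079,7805,26781,A,,,V,L,0
B35,,B-3501,B*35:01,108,0,77,,,,L,L,1
B35,,B-3501,B*35:03,0,0,15,,,,L,L,0
B35,,B-3501,B*35:08,0,0,18,,,,L,L,0
B35,,B-3502,B*35:02,51,0,0,,,,L,F,0
B35,,B-3512,B*35:12,22504,6851,1796,,,,V,L,0
B37,,B-3701,B*37:01,25553,1299,4687,,L,R,V,L,0
B16,B38,B-3801,B*38:01,32166,4992,6075,,L,R,V,L,0
B16,B38,B-3801,B*38:02,34647,6344,7267,,L,R,V,L,0
B16,B39,B3901,B*39:01,30837,4619,2614,,,,V,L,0
B16,B39,B3901,B*39:04,30550,3518,1642,,,,V,L,0
B16,B39,B3901,B*39:05,32537,5497,1965,,,,V,L,0
B16,B39,B3901,B*39:06,25110,2192,1361,,,,V,L,0
B16,B39,B3902,B*39:02,30755,5374,2574,,,,V,L,0
B16,B39,B3902,B*39:13,31688,6277,1924,,,,V,L,0
B40,B60,B-4001,B*40:01,32618,17634,16874,,,,V,L,0
B40,B61,B-4002,B*40:02,33963,10715,10347,,,,V,L,0
B40,B61,B-4002,B*40:03,33470,9815,9508,,,,V,L,0
B40,B61,B-4002,B*40:06,33840,9301,8605,,,,V,L,0
B40,B61,B-4004,B*40:04,33332,5394,6437,,,,L,L,0
B41,,,B*41:01,34777,14571,13564,,,,V,L,0
B41,,,B*41:02,34370,14535,12426,,,,V,L,0
B42,,,B*42:01,31921,15963,27021,A,,,V,L,0
B42,,,B*42:02,33714,14787,25614,A,,,V,L,0
B12,B44,B-4402,B*44:02,32668,81,3995,,L,R,V,L,0
B12,B44,B-4402,B*44:03,33400,73,4760,,L,R,V,L,0
B12,B45,,B*45:01,31859,0,48,,,,L,L,0
B12,B45,,B*50:02,29751,0,0,,,,L,L,0
B46,,,B*46:01,16522,1379,4495,,,,V,L,0
B47,,B-4701,B*47:01,31055,2798,5672,,L,R,V,L,0
B48,,B-4801,B*48:01,33907,15911,16708,,,,V,L,0
B21,B49,,B*49:01,33477,68,3202,,L,R,L,L,0
B21,B50,,B*50:01,31249,0,139,,,,L,L,0
B21,B50,B4005,B*40:05,34004,6217,1826,,,,V,L,0
B5,B51,B-5101,B*51:01,13172,1339,2425,,L,R,V,L,0
B5,B51,B5102,B*51:02,12220,1323,2567,,L,R,V,L,0
B5,B52,,B*52:01,18341,1289,2311,,L,R,V,L,0
B53,,,B*53:01,14208,0,4252,,L,R,L,L,0
B22,B54,,B*54:01,30883,72,19360,A,,,L,L,0
B22,B55,B-5501,B*55:01,32873,390,20954,A,,,L,L,0
B22,B55,B-5501,B*55:02,33357,300,21027,A,,,L,L,0
B22,B55,B-5504,B*55:04,32535,7479,22302,A,,,V,L,0
B22,B56,B-5601,B*56:01,34383,273,21268,A,,,L,L,0
B22,B56,B-5603,B*56:03,33950,2206,21157,A,,,V,L,0
B17,B57,,B*57:01,33283,5910,28271,A,L,R,V,L,0
B17,B57,,B*57:03,34090,8451,26919,A,L,R,V,L,0
B17,B58,,B*58:01,28575,0,22878,A,L,R,L,L,0
B59,,,B*59:01,26852,0,4903,,L,R,L,L,0
B67,,B-6701,B*67:01,31270,7467,26516,A,L,R,V,L,0
B73,,,B*73:01,33134,4159,14909,A,,,M,L,0
B78,,B-7801,B*78:01,11712,1525,963,,,,V,L,0
B81,,,B*81:01,30723,17426,26107,A,,,V,L,0
B82,,,B*82:01,32262,0,18753,A,,,L,L,0
Cw3,Cw9,,C*03:03,26273,29,965,,,,V,L,0
Cw3,Cw10,C-0304,C*03:02,14637,0,538,,,,V,L,0
Cw3,Cw10,C-0304,C*03:04,19173,0,787,,,,V,L,0
Cw4,,C-0401,C*04:01,339,0,233,,,,L,L,1
Cw7,,C-0701,C*07:01,2713,0,469,,,,L,L,1
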