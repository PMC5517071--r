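status,last_follow_up_days,A,B,C,N1,N2
1,495,0,0,0,0,0
1,2783,1,0,0,1,0
1,4169,1,0,0,0,1
0,2070,1,0,0,0,0
1,3091,0,0,0,0,1
0,365,0,0,1,1,1
1,2026,0,1,0,0,0
1,4422,1,0,1,1,0
1,2554,0,1,0,0,0
0,3196,0,0,1,1,0
0,4535,1,0,0,0,0
1,1795,0,0,0,0,0
0,396,0,1,0,0,0
0,1157,0,0,0,0,0
0,4626,0,0,0,1,0
1,1606,0,0,0,0,0
0,578,0,1,1,1,0
1,359,1,0,0,0,0
1,3369,0,0,0,1,0
1,305,1,0,0,0,0
1,316,1,0,0,0,0
1,1656,0,0,0,0,1
0,3987,0,0,1,0,1
1,1910,0,0,0,0,0
1,251,1,0,1,0,0
1,883,0,0,0,0,1
1,127,0,0,0,1,0
0,2192,0,0,1,0,0
1,3517,1,0,0,0,1
1,4330,1,0,1,1,1
1,296,0,1,0,0,0
0,3074,0,0,1,0,0
0,609,0,1,0,0,1
0,3318,0,1,0,0,0
0,3561,1,1,0,0,0
0,5387,0,1,0,0,0
1,1334,0,1,0,1,1
1,1149,0,1,0,0,1
0,700,0,0,1,1,1
1,712,0,0,0,0,0
0,6270,1,0,0,0,0
0,6301,0,1,0,0,1
0,1035,0,0,0,0,0
1,878,0,1,0,0,0
1,189,0,0,0,0,0
0,3287,0,0,0,0,0
1,669,0,0,1,0,0
0,670,0,0,0,0,0
1,4548,0,0,0,0,0
1,972,0,1,0,0,0
1,1417,0,0,0,0,0
0,730,0,0,0,0,0
1,479,0,0,0,1,0
1,555,0,1,0,0,0
1,1832,1,0,0,0,0
0,2709,0,1,0,1,0
1,1318,1,1,0,1,0
0,3926,0,0,0,0,0
0,1370,1,0,0,0,0
1,457,0,0,0,0,0
0,2678,1,0,0,1,0
1,5440,0,0,0,0,1
1,6727,1,1,0,0,0
1,420,0,1,0,0,0
1,1362,1,0,0,0,0
0,5692,1,0,0,0,0
0,5022,0,0,0,0,0
0,3409,1,0,1,1,0
1,228,0,0,0,0,0
1,1403,0,0,0,0,1
0,487,0,0,0,0,0
1,356,0,0,0,0,0
1,3846,0,0,0,0,0
0,974,0,0,1,0,0
1,1164,1,0,0,0,0
1,222,0,0,0,0,0
0,1857,0,0,1,1,0
0,3105,0,0,0,0,0
1,586,0,1,0,1,0
1,3063,1,1,0,1,0
0,1004,0,0,0,0,0
0,3105,1,0,0,1,0
0,2557,0,1,0,1,0
0,2678,0,0,1,0,0
1,324,0,0,1,1,0
0,2678,0,1,0,0,1
1,802,1,1,0,0,0
1,812,0,0,0,0,0
0,2648,0,1,0,1,0
0,1613,0,0,0,1,1
0,365,0,1,0,0,0
1,286,1,1,0,1,0
0,3379,0,0,0,0,0
0,1004,0,0,0,0,0
1,7096,0,0,0,0,0
0,2739,0,1,0,0,0
0,974,1,1,1,0,0
1,334,1,0,0,0,0
0,122,0,1,0,1,0
0,1400,0,0,0,0,0
0,2344,1,0,1,1,0
1,1330,1,0,0,0,1
1,126,1,1,0,0,1
1,2419,1,0,0,0,0
0,3866,0,1,1,0,0
1,2235,1,1,0,0,0
0,1157,0,0,0,1,0
1,376,1,1,0,0,0
1,7284,0,0,0,0,0
1,2,1,0,0,0,1
1,5334,1,1,1,0,0
0,4474,0,0,0,0,1
1,1717,0,0,0,0,1
1,803,0,1,1,0,0
0,1704,1,0,1,0,0
0,2678,0,0,0,0,0
0,2435,0,1,1,0,0
1,1695,0,0,0,0,0
1,2002,0,0,0,0,0
0,791,1,0,1,0,0
1,5493,1,0,0,0,1
0,791,0,1,0,1,1
0,2100,0,0,0,1,0
0,1552,0,1,0,1,1
0,1826,0,0,0,1,0
1,1709,0,0,0,0,0
1,9160,0,0,1,0,0
0,1431,0,0,1,0,0
0,1735,1,1,1,0,0
1,632,0,0,0,0,0
0,335,0,0,0,0,0
0,1461,0,0,1,0,1
0,213,1,0,0,0,0
1,1933,0,1,0,0,0
0,639,1,0,0,0,0
0,2252,1,0,0,1,0
0,1857,0,0,0,0,0
0,6361,1,0,0,0,0
1,609,0,0,0,0,0
0,1704,1,0,1,1,1
1,4699,1,1,0,1,1
1,3265,0,0,1,0,0
0,1826,0,0,0,0,1
0,1461,1,0,0,0,0
0,5631,0,0,0,0,0
0,1278,0,0,0,0,0
1,607,1,0,0,0,0
1,810,0,0,0,0,1
0,2070,0,0,1,0,0
1,785,0,0,0,0,1
0,1887,0,0,1,0,0
0,1065,1,1,1,0,0
0,6453,0,0,1,0,0
1,5398,1,1,0,0,0
0,2405,0,0,0,0,0
1,4883,0,1,0,1,0
1,9079,1,1,0,0,1
1,1749,1,0,0,0,0
1,2282,1,0,1,0,0
0,913,1,0,0,0,0
1,862,0,1,0,0,0
1,684,1,0,0,0,1
1,3178,0,1,1,0,0
1,1878,0,0,0,0,0
0,12662,1,1,0,0,0
0,3013,1,0,1,0,0
1,1547,1,0,1,0,0
0,730,0,1,0,0,1
1,273,0,0,0,0,0
1,371,0,0,1,0,0
0,1004,1,1,0,0,0
0,3896,1,0,0,0,0
1,2861,0,0,0,1,0
0,1370,1,1,1,0,0
0,3348,1,0,1,0,0
0,1431,0,0,0,1,0
0,1461,0,0,0,0,0
1,2073,0,0,0,1,1
0,183,0,0,0,0,0
0,1370,0,0,0,0,0
1,935,1,0,0,0,0
1,2075,1,1,0,1,0
0,6453,0,0,0,1,0
1,211,0,0,1,0,0
1,321,0,1,0,1,1
0,3470,0,0,0,0,0
0,2161,0,1,0,0,1
1,1783,0,0,1,0,0
0,426,0,1,0,0,1
1,2241,0,0,0,0,1
0,1035,0,0,0,0,0
1,7792,1,1,0,0,1
0,1948,0,0,0,0,1
1,1461,0,0,1,1,0
0,3592,0,1,1,0,0
1,577,0,0,0,1,0
1,1153,0,0,0,1,0
1,263,0,0,0,0,0
1,640,0,0,0,0,0
1,802,0,1,1,0,0
1,1014,1,0,0,0,0
0,1796,0,1,0,1,0
1,786,1,0,0,0,0
0,7548,1,0,0,0,0
0,2131,0,0,1,0,0
1,9174,0,0,0,0,0
1,611,0,0,1,1,0
1,2467,0,0,0,0,0
1,516,0,1,0,0,0
0,3957,0,1,1,0,0
1,232,0,0,1,0,0
0,578,0,0,0,0,0
1,1657,1,0,0,0,0
1,9602,0,0,0,0,0
1,1610,1,0,0,0,0
1,1277,0,0,1,0,0
0,1370,1,1,0,1,0
0,396,1,0,0,0,0
0,2313,0,1,0,1,0
1,107,0,0,1,0,0
0,2222,0,0,0,0,0
1,2042,1,0,0,0,0
0,3013,0,1,0,0,0
1,1944,1,1,0,1,1
1,1863,1,1,0,0,1
1,2673,0,0,0,0,1
0,1004,0,0,1,0,0
0,1370,0,0,0,0,0
1,1682,0,1,0,0,0
0,1826,0,0,0,0,1
1,2197,0,0,0,0,0
0,1613,0,0,1,0,1
1,62,0,1,0,0,0
1,5419,1,1,0,0,1
0,1309,0,0,0,0,1
0,1491,0,1,0,0,0
1,5030,0,1,0,0,1
1,1487,0,0,1,0,0
0,213,0,1,0,1,1
1,8446,0,0,0,0,1
0,4292,1,1,1,1,1
1,1659,0,0,0,1,0
0,670,0,1,1,0,0
0,1826,0,1,1,0,0
1,2301,1,0,0,0,0
0,1126,0,0,0,0,1
0,4261,0,0,1,0,0
1,6914,1,1,0,0,0
1,348,0,0,1,1,0
0,6757,0,1,0,1,0
0,1857,0,0,0,0,1
0,7762,0,0,0,1,0
1,2872,0,0,1,1,0
1,1882,0,0,0,1,0
1,256,0,0,0,0,0
1,3770,1,0,0,0,1
0,1096,0,0,1,0,0
0,2222,1,0,1,0,0
0,4109,0,1,1,0,0
0,852,0,1,0,1,0
1,690,1,0,1,0,0
0,3013,0,0,0,1,1
0,6757,0,0,0,0,0
1,2744,0,1,0,0,1
0,1065,1,1,0,0,0
1,3108,0,1,0,0,0
0,3379,0,0,0,0,0
0,335,0,0,0,1,0
1,3469,0,1,1,0,1
1,1742,0,0,1,1,0
0,2770,0,0,0,0,1
0,1339,1,0,0,0,0
1,1204,0,0,0,1,1
0,1522,0,0,0,0,1
0,3013,0,1,0,1,1
1,4437,0,0,0,0,0
1,6501,0,0,0,0,0
0,4140,1,0,0,0,0
0,730,1,1,1,0,0
1,797,1,0,0,0,0
1,610,1,0,0,0,0
0,3805,0,0,0,0,0
1,6669,0,0,1,0,0
1,9157,1,1,0,1,0
0,61,1,0,0,1,0
0,2983,1,0,1,0,0
1,2373,1,1,0,1,0
0,1126,1,1,1,0,0
0,365,0,1,0,0,0
0,3409,1,0,0,0,0
1,572,0,0,0,0,0
1,158,0,0,0,0,0
1,39,1,0,0,0,0
0,578,1,0,0,0,0
1,3215,0,0,1,0,0
0,1613,0,1,1,1,0
1,1771,0,0,0,0,0
0,2465,1,1,1,0,0
0,4261,1,1,0,0,1
0,1644,0,0,0,0,0
1,4184,0,1,0,0,0
1,1322,0,1,0,0,0
0,1978,0,0,0,0,0
0,1004,0,0,0,0,1
0,426,0,1,0,0,0
1,1958,0,0,0,0,0
0,1644,0,0,0,0,1
1,3187,1,0,0,0,0
0,883,0,0,0,0,0
0,4200,0,0,0,0,0
0,2465,0,0,1,0,1
0,457,0,0,1,0,0
0,3592,0,1,0,0,1
1,68,0,0,0,1,1
0,426,0,0,0,0,1
0,1096,0,0,0,0,0
0,2892,0,0,0,0,1
0,3805,0,1,1,1,0
1,203,1,0,0,0,1
0,91,1,0,1,0,0
1,4916,1,1,0,0,0
0,761,0,0,1,0,0
0,30,1,1,1,0,0
1,491,0,0,1,0,1
0,700,0,1,0,0,0
0,1918,1,1,1,0,1
0,639,0,1,0,0,0
1,9419,1,1,0,0,0
1,1326,0,0,1,0,0
0,2039,0,1,0,0,0
1,95,0,0,0,0,0
0,4931,1,0,0,0,0
0,2161,0,1,1,0,1
1,6128,0,0,1,0,1
0,1857,1,0,1,0,0
1,306,0,1,0,0,0
0,11992,0,0,0,1,0
0,1065,0,0,0,0,0
0,1309,0,0,0,0,1
0,2465,0,0,0,1,0
0,2922,0,1,0,0,0
1,4953,0,0,0,1,0
0,1035,0,1,1,0,0
1,2297,1,0,0,0,0
1,649,1,1,0,0,1
0,609,1,0,0,0,1
1,460,1,0,0,0,0
1,1238,0,0,0,0,0
1,1690,0,0,0,0,0
0,609,0,0,0,0,0
1,1471,1,0,0,1,0
1,4266,0,0,0,1,0
0,244,1,0,0,0,0
1,3203,1,0,1,0,0
0,365,0,0,0,0,0
1,1268,0,1,0,0,0
1,1435,0,0,1,0,1
1,3661,1,0,0,0,0
1,734,0,1,0,1,0
0,365,1,0,1,0,0
0,974,0,0,0,0,0
1,588,0,0,0,0,1
1,1039,0,1,0,1,0
0,2892,0,1,1,1,0
0,1491,1,0,0,0,0
0,1522,1,0,1,0,0
1,725,0,1,0,0,0
1,4631,1,0,1,0,0
0,2526,1,1,0,0,0
0,1218,0,1,0,0,0
0,7001,1,1,0,0,1
0,2405,0,0,0,0,1
0,1735,1,1,1,0,0
0,1126,1,0,1,0,0
1,1125,0,0,0,0,1
1,615,1,0,0,0,1
0,2283,0,0,1,0,0
1,286,1,1,0,0,0
1,8319,0,0,0,1,0
0,3683,0,0,0,1,0
0,122,0,0,0,0,1
1,1239,0,0,1,0,0
0,335,1,0,0,0,0
1,716,0,0,0,1,1
1,10,0,1,0,0,0
1,2785,0,1,0,0,1
1,1799,0,0,0,0,0
0,883,0,1,0,1,1
0,1613,1,1,0,0,0
0,3044,0,1,0,0,0
1,2975,1,0,0,0,0
1,583,0,1,0,0,0
1,3789,0,0,1,0,0
0,244,1,1,0,0,0
1,3910,0,0,0,0,0
1,6248,1,1,0,0,0
0,4140,0,0,1,1,0
1,1323,1,0,0,0,0
0,4048,1,0,0,1,0
1,1243,0,0,0,0,1
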