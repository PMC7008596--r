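donor,side,condition,ct_volume_mm3,aoct_volume_mm3,dsc,hd_mm
1,left,preintervention,1664.96,1699.89,0.905,2.087
1,left,post_SG,1346.63,1345.12,0.872,2.721
1,left,post_BFG,2464.13,2619.59,0.919,2.877
1,right,preintervention,812.43,1002.79,0.790,2.721
1,right,post_SG,1392.31,1343.94,0.873,2.113
1,right,post_BFG,1446.61,1510.32,0.870,1.952
2,left,preintervention,1422.49,1481.11,0.872,2.310
2,left,post_SG,1439.42,1467.60,0.788,2.701
2,left,post_BFG,1829.23,1615.48,0.877,2.007
2,right,preintervention,1360.61,1466.45,0.885,2.310
2,right,post_SG,1558.48,1598.19,0.880,1.980
2,right,post_BFG,2071.37,1894.49,0.928,1.896
3,left,preintervention,1117.53,1044.76,0.855,2.139
3,left,post_SG,1879.07,1801.59,0.884,2.661
3,left,post_BFG,1638.22,1639.52,0.883,3.006
3,right,preintervention,1707.01,1523.98,0.898,1.320
3,right,post_SG,1542.88,1493.47,0.917,1.896
3,right,post_BFG,1446.79,1337.65,0.917,1.476
4,left,preintervention,1975.71,1925.79,0.885,2.970
4,left,post_SG,2476.56,2486.88,0.930,1.867
4,left,post_BFG,1829.80,1303.43,0.806,4.290
4,right,preintervention,1875.48,1753.19,0.905,1.867
4,right,post_SG,1815.61,1739.60,0.939,1.896
4,right,post_BFG,1804.94,1650.41,0.911,1.896
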