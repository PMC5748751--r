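id,split,ppapp_exp,ppapp_pred,E_sol,SlogP_V3,QC3p,vsurf_ID1,residual
1,training,4.651,4.756,-0.789,0,0.010,0.736,-0.105
2,training,4.660,4.947,-1.802,0,-0.019,4.097,-0.287
3,training,4.784,4.803,1.526,0,0.011,1.561,-0.019
5,training,4.820,4.663,-3.225,0,0.305,0.474,0.157
6,training,4.766,4.751,-0.893,0,-0.007,0.636,0.015
7,training,5.169,5.197,0.986,0,0.011,8.594,-0.028
8,training,5.484,5.709,-2.750,41.853,-0.004,2.774,-0.225
10,training,5.594,5.278,0.378,25.386,0.301,0.822,0.316
11,training,5.085,5.243,0.104,25.386,-0.033,0.359,-0.158
15,training,5.962,5.322,1.610,25.386,0.322,1.034,0.640
16,training,5.373,5.041,-2.100,0,0.272,6.626,0.332
17,training,5.394,5.363,-10.491,20.927,0.276,8.232,0.031
18,training,4.629,4.750,1.351,0,-0.028,0.685,-0.121
19,training,4.493,4.754,-1.043,0,-0.018,0.669,-0.261
21,training,4.509,4.731,-2.117,0,-0.019,0.228,-0.222
22,training,5.199,4.755,-0.789,0,0.302,1.064,0.444
23,training,4.759,4.735,-1.910,0,-0.012,0.334,0.024
24,training,5.648,5.370,1.320,20.927,-0.034,4.292,0.278
25,training,4.905,4.749,-1.314,0,-0.023,0.553,0.156
26,training,4.470,4.730,-2.317,0,-0.023,0.190,-0.260
28,training,4.954,4.753,0.600,0,-0.006,0.690,0.201
29,training,4.861,4.765,-1.601,0,-0.013,0.861,0.096
9,test,5.712,5.347,3.668,25.386,0.005,2.195,0.365
12,test,5.175,5.254,2.066,25.386,0.005,0.548,-0.079
14,test,6.535,5.376,3.979,25.386,0.295,1.045,1.159
20,test,5.429,5.514,-6.238,20.927,-0.034,6.492,-0.085
27,test,4.508,4.745,-0.205,0,-0.022,0.527,-0.237
30,test,5.372,5.062,-10.370,20.926,0.291,3.024,0.310
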