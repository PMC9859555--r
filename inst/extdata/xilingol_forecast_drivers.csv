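year,month,SE,P,LAI,VCR,IC_ref,dbeta_ref
2022,4,10.8614,0.0000,0.7270,0.0140,0.0000,-10.8614
2022,5,18.3533,65.4249,0.7390,0.0319,0.0452,-16.2177
2022,6,23.1401,77.9889,0.8270,0.0919,0.1304,-20.6709
2022,7,27.0137,89.3870,0.9640,0.2348,0.3332,-24.3674
2022,8,17.4328,69.7163,0.9830,0.2893,0.4106,-15.5195
2022,9,13.1105,81.2433,0.8470,0.1724,0.2447,-10.6471
2022,10,8.8015,64.5582,0.7380,0.0582,0.0825,-6.7321
2022,11,2.3674,230.9857,0.7100,0.0102,0.0144,5.3177
2022,12,0.9876,125.7876,0.6480,0.0007,0.0010,3.2044
2023,1,0.6344,257.7069,0.6364,0.0059,0.0083,7.9474
2023,2,0.7005,292.5912,0.6507,0.0021,0.0030,9.0495
2023,3,4.5560,88.0504,0.7168,0.0120,0.0170,-1.6379
2023,4,9.9031,57.6033,0.7270,0.0186,0.0264,-8.0093
2023,5,18.0552,83.1367,0.7390,0.0420,0.0596,-15.3435
2023,6,23.0474,83.1367,0.8270,0.1080,0.1532,-20.4294
2023,7,26.9849,83.1367,0.9640,0.2814,0.3992,-24.6129
2023,8,17.4238,83.1367,0.9830,0.3535,0.5016,-15.1542
2023,9,13.1078,83.1367,0.8470,0.2137,0.3033,-10.6398
2023,10,8.8006,83.1367,0.7380,0.0701,0.0994,-6.1288
2023,11,2.3671,83.1367,0.7100,0.0078,0.0111,0.3930
2023,12,0.9875,83.1367,0.6480,0.0002,0.0002,1.7835
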