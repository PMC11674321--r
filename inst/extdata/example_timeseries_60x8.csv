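 2.2872, 1.0102,-0.5219, 2.3573,-0.5496, 0.8489, 0.4467,-1.7531
-1.1968,-0.3471, 0.9997, 2.0555, 0.2032,-0.5245,-2.3497, 0.9736
-0.6943, 0.2101, 0.5464, 1.0392, -0.949,-0.3409,-1.0125,-0.0039
-0.4123, 0.4729,-0.0496, -0.213, 1.4162, 0.1732, 0.9677, 1.7112
-0.9707,-0.1084, 0.4057, 0.3261,-0.3549,-0.6643,-0.1537,-0.6461
-0.9473, 0.6216, 1.3906,-0.2049, 2.1233,-0.6581, 0.1654, 1.4519
 0.7481, 1.0088, 0.9728, 1.4721,-0.4531,  1.549,-0.0408, 0.7961
 -0.117, 1.0033, 0.3951, 0.5793,-0.1134,-0.1292,  0.302,-0.5953
 0.1527, 1.2119,-0.7751,-1.6591,-1.9697,-1.0935, 0.7729,-0.8909
   2.19, 1.5392, 1.8979, 0.5477, 1.2993, 1.4794, 1.3903, 1.6068
  0.357, 0.5412,-0.2373,-1.6373,-1.4098, 0.6235,-1.4843,-0.0839
 2.7168, 0.2762, 1.3298, 2.0261,-2.4288, 0.3587,-0.9669,-0.5191
 2.2815, 0.3771, 1.3325, 0.6387,-0.8125,  1.312,-0.1466, 0.0474
  0.324,-0.6567, 0.1271,-0.9368,-0.0756,-2.6963,-0.7488,-0.5368
 1.8961,-0.7147, 1.0694, 0.5195, 0.1185, 0.3562, 0.3725,  0.894
 0.4677,-1.0162,-0.9613, 0.0207,-0.6938, 0.8985,-0.6762,-1.6898
-0.8938,-1.1779,-0.2402,-1.1581,-0.5964,-0.1089, -0.104, 0.5569
-0.3073,-0.6347, 0.4905,-0.0425, 1.8619, -0.799, 0.8324,-0.4312
-0.0048,-0.0589, 0.2104,-0.4592, 0.0688,-0.3827, 0.5597, 1.3689
 0.9882, 2.6147, 2.0752, 1.6524, 0.4335,-1.0228,-1.5447,-1.4531
 0.8398, 0.6576,-0.8534, 1.7815,-1.0478, -0.904,-1.3921,-1.2243
 0.7053, 0.2939,-0.5108, 0.7891,-1.6416,-0.8799, 0.7252, 1.1321
  1.306, 0.5637, 0.6106, 0.4796, 2.8621, 3.0652,  2.462, 1.7399
 -1.388,-0.9294,-0.4447, 0.0177, 0.8548, 0.1642, 0.8472, 0.2477
 1.2729,-0.1991, 0.5841, 1.4739,  1.089, 0.9767, 0.4073, 1.0448
 0.1842,-0.2084,-0.1078,-1.0533, 0.5284,-0.4399, 0.5455,-1.2392
 0.7523,-0.0061,-0.6303,-0.5657,-0.6547, 0.1118, -1.573,-1.6591
 0.5917,-0.0343, 0.5212, 0.6061, 0.1975,-0.5699,  0.476,-0.7497
-0.9831,-2.0322,-0.6788,-1.8522,-0.8382,-1.5539, -1.556,-0.9438
-0.2761, 0.4218, -0.842, 0.8362, 0.9636, 0.0541, 0.7314,-0.3055
-0.8709,  1.133,-0.0359,-0.0463, 0.5835, 1.0075, 0.0826,-0.8432
 0.7187,-0.2928, 0.9758,-1.0362, 0.7185,-0.3223, 0.2563, 1.8162
 0.1107, 0.6097,-0.5296,-0.6474,-0.3286, 0.9898,-0.3168,-0.8124
-0.0785, 0.1832, -0.124,-0.5373,-1.0769,-0.0982,-0.9804,-0.5682
-0.4205, 0.5987, 0.7408,-0.6009, 0.2727, -0.037, 0.1147, 1.1345
-0.5621,-0.7541,-1.0914, 0.8041, 2.0722,-0.1246, 1.6507,-0.4572
 0.9975, 1.4293,-0.6374, 0.0578, 0.6864,-0.3158, 1.3956,-1.2992
-1.1051,-1.8582,  0.094,-0.3084, 0.8315, 0.6669,-0.5957,-0.3298
-0.1423,-0.4579, 0.8565,-0.7468, 1.6673, 0.2968,  0.165,  0.842
  0.315,-0.0078, 0.0476,-0.3154,  1.274, 1.4631, 1.6821, 0.2605
 1.2186, 0.9742, 0.9094, 0.4424, 2.2737,-0.0471, 1.0291,  0.253
-0.6993,  0.248, 0.0444,-1.2193, 0.6842, -0.832,  1.103,-0.1416
-0.2854,-0.1897, -0.122, 0.7263,-1.5133,-2.0048,-1.7432,-0.3926
-1.3116,-1.6098, -0.229,-0.0939,-0.5972,-2.0746,-0.1521, 0.4999
 -0.391, 0.1206, 0.8765,-0.3071,  0.332,-0.8791, 0.6998, 0.0939
-0.4015,-1.6271,-0.9837, 0.5502,-0.6681, 0.6563, 0.2944,-1.1243
 1.3505,  1.459, 1.1024, 0.7376, 0.3764, 1.4305, 0.7654,-0.1281
 0.5912, 1.1758, 1.1625,-0.1144, 0.6805, 0.3985, 1.3973, 0.2098
 0.1005, 0.8072, 0.6096,-0.0691, -0.062, 0.1374,-0.1814, 1.2065
 0.9311, 0.4923,-1.2936,-1.7979, 0.7582, 1.1792, 0.4799,-0.5984
-0.2627,-0.4966,-2.2729, 0.0976,-1.2208, 0.4797,-0.0355,-0.5428
-0.0077, 0.4152, 0.5783,-0.2426,  1.711, 0.4241,-0.4896,-0.1537
 0.3672,  0.739, 1.3788, 0.5639,-0.7476,-1.6083,-0.7315,-0.3223
 1.7072, 1.2595,-0.3087, 0.1674, -0.058, 1.1812, 0.8069,-1.4098
 0.7237,-0.5129, 0.4737, 1.5658,-1.6628,-0.9675,-1.3607, 1.4184
  0.481, 1.6051, 0.9354,-0.7542, 0.1997,-0.1134, 0.4967, 0.0373
-1.5679,-1.7767,-0.3553,-0.6313,-0.2738,-0.9821,-1.2974, 0.2307
 0.3183, 1.1367, 1.6498, 0.6847,-0.5828,  -2.02,-0.9535, 1.1132
  0.166, 0.9641, 0.5327, 0.2923,-2.0596,-1.4172,-1.6428,-0.8914
-0.8999,-0.0927,-0.7268,-0.7825,-0.8451, 1.9261,-0.5984,  0.143
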