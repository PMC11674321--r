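roi_1,roi_2,roi_3,roi_4,roi_5,roi_6,roi_7,roi_8
      0,0.437096,0.365295,0.363286,0.125576,0.115243,0.122696,-0.0390654
0.437096,      0,0.504469,0.340427,0.045267,0.164332,0.053681,0.0414041
0.365295,0.504469,      0,0.434081,0.226382,-0.0291646,-0.186351,0.166101
0.363286,0.340427,0.434081,      0,0.0468643,0.0360606,-0.108035,0.14476
0.125576,0.045267,0.226382,0.0468643,      0,0.286668,0.648017,0.256953
0.115243,0.164332,-0.0291646,0.0360606,0.286668,      0,0.404004,0.274273
0.122696,0.053681,-0.186351,-0.108035,0.648017,0.404004,      0,0.185526
-0.0390654,0.0414041,0.166101,0.14476,0.256953,0.274273,0.185526,      0
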