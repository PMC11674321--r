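roi_label	network
roi_1	DMN
roi_2	DMN
roi_3	DMN
roi_4	DMN
roi_5	VIS
roi_6	VIS
roi_7	VIS
roi_8	VIS
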