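,p1,p2,p3,p4,p5,p6,p7,p8
p1,,0.375,0.25,0.125,0,0.125,0,0.75
p2,0.625,,-0.25,0,0.625,0.875,0.125,0.375
p3,0.625,-0.125,,0.75,-0.125,0.875,0.125,-0.25
p4,0.125,-0.25,0.125,,0.125,0.25,0.375,0.125
p5,0.125,0.625,0.625,0.125,,-0.125,0,1
p6,-0.125,0.875,0.875,0.5,-0.25,,-0.125,0.5
p7,0.625,0.125,0.25,-0.125,-0.125,0.125,,-0.125
p8,-0.25,0.625,-0.25,-0.125,0.75,0.125,0,
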