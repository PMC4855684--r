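"ego","alter","time_outside","work_with","confide","nature","trust"
"p1","p2",1,1,0,1,0
"p1","p3",0,1,0,1,0
"p1","p4",0,0,0,1,0
"p1","p5",0,0,0,0,0
"p1","p6",0,0,0,1,0
"p1","p7",0,0,0,0,0
"p1","p8",1,1,1,2,1
"p2","p1",1,1,1,2,0
"p2","p3",0,0,0,-1,-1
"p2","p4",0,0,0,0,0
"p2","p5",1,1,1,2,0
"p2","p6",1,1,1,3,1
"p2","p7",0,0,0,1,0
"p2","p8",1,1,0,1,0
"p3","p1",1,1,1,2,0
"p3","p2",0,0,0,0,-1
"p3","p4",1,1,1,2,1
"p3","p5",0,0,0,0,-1
"p3","p6",1,1,1,3,1
"p3","p7",0,0,0,1,0
"p3","p8",0,0,0,-1,-1
"p4","p1",0,0,0,1,0
"p4","p2",0,0,0,-1,-1
"p4","p3",0,0,0,1,0
"p4","p5",0,0,0,1,0
"p4","p6",0,1,0,1,0
"p4","p7",1,1,0,1,0
"p4","p8",0,0,0,1,0
"p5","p1",0,0,0,1,0
"p5","p2",1,1,1,2,0
"p5","p3",1,1,1,2,0
"p5","p4",0,0,0,1,0
"p5","p6",0,0,0,0,-1
"p5","p7",0,0,0,0,0
"p5","p8",1,1,1,4,1
"p6","p1",0,0,0,0,-1
"p6","p2",1,1,1,3,1
"p6","p3",1,1,1,3,1
"p6","p4",1,1,0,2,0
"p6","p5",0,0,0,-1,-1
"p6","p7",0,0,0,0,-1
"p6","p8",1,1,0,2,0
"p7","p1",1,1,1,2,0
"p7","p2",0,0,0,1,0
"p7","p3",0,1,0,1,0
"p7","p4",0,0,0,0,-1
"p7","p5",0,0,0,0,-1
"p7","p6",0,0,0,1,0
"p7","p8",0,0,0,0,-1
"p8","p1",0,0,0,-1,-1
"p8","p2",1,1,1,2,0
"p8","p3",0,0,0,-1,-1
"p8","p4",0,0,0,0,-1
"p8","p5",1,1,1,2,1
"p8","p6",0,0,0,1,0
"p8","p7",0,0,0,0,0
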