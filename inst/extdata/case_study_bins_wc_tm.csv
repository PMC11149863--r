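true_class,Mb,Zc,Mm,BWG,Md,Me,De spp,Gg,Ko spp,Pm & Boat,ES ping,No label
Mb,391,0,26,0,0,5,23,1,3,2,0,17
Zc,1,304,1,0,0,0,42,1,0,1,4,42
Mm,5,0,147,0,0,2,5,0,1,0,0,14
Mm | Me,0,0,8,0,0,0,0,0,0,0,0,0
No label,244,269,216,99,30,41,10837,1102,306,6642,225,1435
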