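true_class,Mb,Zc,Mm,BWG,Md,Me,De spp,Gg,Ko spp,Pm & Boat,ES ping,No label
Mb,393,1,6,2,0,0,12,0,0,0,0,11
Zc,0,326,2,4,0,2,27,7,1,1,3,5
Mm,4,2,143,0,0,9,4,1,2,0,0,3
Mm | Me,0,0,9,0,0,2,0,0,0,0,0,0
No label,9,160,22,176,55,21,1147,161,4,33,47,891
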