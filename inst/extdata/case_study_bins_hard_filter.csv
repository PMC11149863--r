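true_class,Mb,Zc,Mm,Me,Md,BWG,De spp,Gg,Ko spp,Pm & Boat,ES ping,No label
Mb,766,1,14,1,2,6,27,1,3,2,0,30
Zc,1,1188,20,13,6,20,61,20,1,1,3,12
Mm,4,6,315,11,0,5,9,1,3,0,0,5
Me,3,51,486,2563,4,82,32,3,7,0,1,0
Md,0,0,0,1,2,1,3,0,0,0,0,0
Mm | Me,0,1,32,5,0,3,2,0,0,0,0,0
Md | Me,0,0,0,1,0,0,0,0,0,0,0,0
likely Me,0,0,0,0,0,1,0,0,0,0,0,0
likely Md,0,0,0,0,0,1,1,0,1,0,0,0
No label,28,604,809,231,713,2671,4309,2195,165,22,97,4772
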