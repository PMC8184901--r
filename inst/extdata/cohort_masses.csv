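patient,side,provenance,value
1,left,expert,148
2,left,expert,102
3,left,expert,254
4,left,expert,147
5,left,expert,99
6,left,expert,142
7,left,expert,107
8,left,expert,184
1,right,expert,148
2,right,expert,166
3,right,expert,NA
4,right,expert,160
5,right,expert,122
6,right,expert,127
7,right,expert,90
8,right,expert,178
1,left,ai,169
2,left,ai,93
3,left,ai,243
4,left,ai,125
5,left,ai,95
6,left,ai,138
7,left,ai,102
8,left,ai,188
1,right,ai,166
2,right,ai,184
3,right,ai,NA
4,right,ai,137
5,right,ai,124
6,right,ai,104
7,right,ai,90
8,right,ai,170
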