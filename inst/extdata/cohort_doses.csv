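patient,side,provenance,value
1,left,expert,1.79
2,left,expert,1.72
3,left,expert,1.89
4,left,expert,1.77
5,left,expert,2.83
6,left,expert,3.49
7,left,expert,2.19
8,left,expert,2.00
1,right,expert,1.61
2,right,expert,1.50
3,right,expert,NA
4,right,expert,1.57
5,right,expert,2.52
6,right,expert,3.39
7,right,expert,2.66
8,right,expert,2.01
1,left,ai,1.77
2,left,ai,1.56
3,left,ai,1.85
4,left,ai,1.82
5,left,ai,2.82
6,left,ai,3.34
7,left,ai,1.74
8,left,ai,2.16
1,right,ai,1.55
2,right,ai,1.42
3,right,ai,NA
4,right,ai,1.73
5,right,ai,2.54
6,right,ai,3.56
7,right,ai,1.87
8,right,ai,2.08
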