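day,animal,mfc,str
0,1,7,9
0,2,7,9
0,3,15,14
0,4,11,8
0,5,3,4
0,6,6,8
0,7,10,15
1,1,5,5
1,2,7,9
1,3,8,9
1,4,5,2
1,5,3,5
1,6,6,8
1,7,13,20
2,1,7,4
2,2,6,7
2,3,7,8
2,4,6,3
2,5,4,3
2,6,6,8
2,7,11,21
3,1,10,6
3,2,6,11
3,3,11,13
3,4,9,4
3,5,4,8
3,6,10,11
3,7,14,27
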