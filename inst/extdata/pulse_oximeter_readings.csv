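group,patient,reading_index,spo2
1,P1,1,97
1,P1,2,96
1,P1,3,97
1,P1,4,95
1,P1,5,97
1,P2,1,96
1,P2,2,95
1,P2,3,96
1,P2,4,96
1,P2,5,95
1,P3,1,99
1,P3,2,99
1,P3,3,98
1,P3,4,98
1,P3,5,99
1,P4,1,90
1,P4,2,91
1,P4,3,92
1,P4,4,90
1,P4,5,90
1,P5,1,97
1,P5,2,96
1,P5,3,97
1,P5,4,97
1,P5,5,96
1,P6,1,97
1,P6,2,95
1,P6,3,96
1,P6,4,97
1,P6,5,97
1,P7,1,90
1,P7,2,91
1,P7,3,91
1,P7,4,90
1,P7,5,90
1,P8,1,97
1,P8,2,95
1,P8,3,96
1,P8,4,97
1,P8,5,97
2,P1,1,97
2,P1,2,97
2,P1,3,96
2,P1,4,96
2,P1,5,97
2,P2,1,96
2,P2,2,96
2,P2,3,96
2,P2,4,96
2,P2,5,95
2,P3,1,98
2,P3,2,99
2,P3,3,99
2,P3,4,98
2,P3,5,99
2,P4,1,90
2,P4,2,91
2,P4,3,92
2,P4,4,90
2,P4,5,90
2,P5,1,97
2,P5,2,96
2,P5,3,97
2,P5,4,97
2,P5,5,96
2,P6,1,97
2,P6,2,97
2,P6,3,96
2,P6,4,97
2,P6,5,97
2,P7,1,90
2,P7,2,91
2,P7,3,91
2,P7,4,90
2,P7,5,90
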