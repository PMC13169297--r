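name	class	theta	phi
4C1	C	0	0
1C4	C	180	0
3,OB	B	90	0
3S1	S	90	30
B1,4	B	90	60
5S1	S	90	90
2,5B	B	90	120
2SO	S	90	150
B3,O	B	90	180
1S3	S	90	210
1,4B	B	90	240
1S5	S	90	270
B2,5	B	90	300
OS2	S	90	330
OE	E	54.73561	0
EO	E	125.26439	180
1E	E	125.26439	240
E1	E	54.73561	60
2E	E	54.73561	120
E2	E	125.26439	300
3E	E	125.26439	0
E3	E	54.73561	180
4E	E	54.73561	240
E4	E	125.26439	60
5E	E	125.26439	120
E5	E	54.73561	300
OH1	H	50.76848	30
1HO	H	129.23152	210
1H2	H	129.23152	270
2H1	H	50.76848	90
2H3	H	50.76848	150
3H2	H	129.23152	330
3H4	H	129.23152	30
4H3	H	50.76848	210
4H5	H	50.76848	270
5H4	H	129.23152	90
5HO	H	129.23152	150
OH5	H	50.76848	330
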