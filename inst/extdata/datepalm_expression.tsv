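gene	strand	leaf	root	bud
psbA	N	44(100)	-	2(71.1)
matK	N	107(100)	57(100)	2(100)
rps16	N	122(100)	120(100)	105(100)
psbK	P	6(100)	-	-
psbI	P	13(100)	-	-
atpA	N	143(100)	28(100)	6(100)
atpF	N	15121(100)	3030(100)	91(100)
atpH	N	96(100)	20(100)	7(100)
atpI	N	67(100)	10(100)	6(100)
rps2	N	14(100)	6(100)	2(64.7)
rpoC2	N	30(100)	29(99.5)	4(91.1)
rpoC1	N	84(96.5)	63(100)	9(98.3)
rpoB	N	59(100)	47(100)	5(64)
petN	P	5(100)	5(100)	2(100)
psbM	N	5(100)	2(100)	2(100)
psbD	P	165(100)	5(72.5)	2(90.7)
psbC	P	140(100)	5(78.2)	-
psbZ	P	233(100)	19(100)	2(100)
rps14	N	39(100)	-	-
psaB	N	150(100)	16(100)	-
psaA	N	29(100)	7(100)	2(68.7)
ycf3	N	268(100)	177(100)	4(78.9)
rps4	N	5(84.8)	1(84.7)	-
ndhJ	N	19(100)	8(100)	3(100)
ndhK	N	9(100)	4(97.7)	2(74.9)
ndhC	N	13(100)	4(100)	-
atpE	N	144(100)	20(100)	4(100)
atpB	N	114(81.7)	14(87.4)	7(100)
rbcL	P	158(100)	12(100)	9(95.4)
accD	P	25(100)	47(100)	12(99.9)
psaI	P	1(82)	1(82)	-
ycf4	P	64(100)	12(100)	3(100)
cemA	P	7(97.6)	7(97.6)	-
petA	P	50(100)	17(100)	2(50.8)
psbJ	N	8(100)	3(100)	1(97.6)
psbL	N	10(100)	4(100)	1(100)
psbF	N	8(100)	1(100)	-
psbE	N	11(100)	1(100)	-
petL	P	1(76)	1(100)	-
petG	P	7(100)	3(100)	-
psaJ	P	76(100)	16(100)	1(88.9)
rpl33	P	41(100)	24(100)	-
rps18	P	10(100)	2(100)	-
rpl20	N	35(100)	34(100)	-
rps12_5end	N	20(100)	15(100)	2(100)
clpP	N	151(100)	174(100)	18(100)
psbB	P	34(100)	5(100)	6(100)
psbT	P	14(100)	-	-
psbN	N	37(100)	-	-
psbH	P	73(100)	2(100)	-
petB	P	19(100)	2(77.5)	2(62.4)
petD	P	12(100)	5(98.7)	-
rpoA	N	61(100)	21(100)	3(100)
rps11	N	121(100)	15(100)	-
rpl36	N	8(100)	2(100)	1(100)
infA	N	30(100)	10(100)	-
rps8	N	24(100)	8(100)	-
rpl14	N	43(100)	30(100)	3(100)
rpl16	N	14(100)	8(97.8)	3(100)
rps3	N	40(100)	24(100)	4(100)
rpl22	N	40(100)	18(100)	4(100)
rps19	N	19(90.3)	8(90.3)	5(90.3)
rpl2	N	238(100)	122(100)	7(100)
rpl23	N	19(100)	3(97.9)	1(100)
ycf2	P/N	17(100)	35(84.3)	16(97.8)
ndhB	N/P	25(88.5)	14(70.7)	-
rps7	N/P	317(100)	85(100)	11(100)
rps12_3end	N/P	126(100)	32(100)	9(100)
ndhF	N	2(66.1)	5(60.9)	-
rpl32	P	-	-	-
ccsA	P	2(98)	4(97.7)	2(91.5)
ndhD	N	17(72.5)	-	5(100)
psaC	N	5(100)	3(100)	-
ndhE	N	-	-	-
ndhG	N	-	-	-
ndhI	N	8(100)	4(98.7)	-
ndhA	N	21(100)	6(100)	-
ndhH	N	18(100)	6(100)	-
rps15	N	4(87.9)	1(95.2)	-
ycf1	N	33(100)	32(100)	14(100)
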