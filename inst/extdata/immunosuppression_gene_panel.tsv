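gene	chrom	start	end	subgroups
TNFRSF18	1	1138888	1142071	Treg
TGFBR3	1	92145000	92370000	Treg,tDC
CD160	1	144151577	144171515	Costim
IL10	1	205006000	205011000	Treg,tDC,Secreted
TGFB2	1	216586000	216682000	Treg,tDC,Secreted
CD28	2	204279000	204310000	Treg,Costim
CTLA4	2	204440000	204446000	Treg,Costim
ICOS	2	204509000	204534000	Treg,Costim
PDCD1	2	242440000	242450000	Costim
TGFBR2	3	30622000	30710000	Treg,tDC
IL17RB	3	53855000	53873000	Treg
CBLB	3	106800000	107010000	Anergy
BTLA	3	113700000	113734000	Costim
CD80	3	120750000	120785000	Costim
CD86	3	123260000	123325000	Costim
IL12A	3	161200000	161207000	Secreted
IL12B	5	158674000	158690000	Secreted
BTNL2	6	32470000	32482000	Costim
TREML2	6	41180000	41195000	Costim
IL17A	6	52159000	52163000	Treg,Secreted
IDO1	8	39890000	39905000	Treg,tDC,Secreted
CD274	9	5440000	5460000	Costim
PDCD1LG2	9	5500000	5560000	Costim
TGFBR1	9	100907000	100956000	Treg,tDC
IL10RA	11	117360000	117375000	Treg,tDC
VDR	12	46521000	46585000	Treg,tDC
DGKA	12	54700000	54722000	Anergy
LGALS3	14	54660000	54677000	Secreted
CCL22	16	55930000	55938000	Treg,Secreted
CCL17	16	55980000	55991000	Treg,Secreted
IL12RB1	19	18033000	18073000	Treg
TGFB1	19	46540000	46563000	Treg,tDC,Secreted
LILRB2	19	59450000	59457000	tDC
LILRB4	19	59770000	59783000	tDC
ITCH	20	32370000	32520000	Anergy
CD40	20	44180000	44192000	Costim
ICOSLG	21	44430000	44447000	Costim
IL10RB	21	33550000	33580000	Treg,tDC
IL17RA	22	15950000	15980000	Treg
LGALS1	22	36400000	36404000	Secreted
FOXP3	X	48990000	49005000	Treg
RNF128	X	105850000	105955000	Anergy
CD40LG	X	135600000	135612000	Costim
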