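code	name	formula	placement	targets	sugar_part	isobaric
mC?	cytidine monomethylation (sugar or base)	CH2	either	C		m5C,m3C,m4C,Cm
mA	adenosine monomethylation (base only)	CH2	base	A		m1A,m6A,m2A,m8A
mA?	adenosine monomethylation (sugar or base)	CH2	either	A		m1A,m6A,Am
mU?	uridine or pseudouridine monomethylation (sugar or base)	CH2	either	U		m5U,m3U,m1Y,Um,m3Y
mG?	guanosine monomethylation (sugar or base)	CH2	either	G		m1G,m2G,m7G,Gm
m5C	5-methylcytidine	CH2	base	C		m5C
Um	2'-O-methyluridine	CH2	sugar	U		Um
m6,6A	N6,N6-dimethyladenosine	C2H4	base	A		m6,6A
m2,2G	N2,N2-dimethylguanosine	C2H4	base	G		m2,2G
t6A	N6-threonylcarbamoyladenosine	C5H7NO4	base	A		t6A
ms2t6A	2-methylthio-N6-threonylcarbamoyladenosine	C6H9NO4S	base	A		ms2t6A
mcm5s2U	5-methoxycarbonylmethyl-2-thiouridine	C3H4OS	base	U		mcm5s2U
D	dihydrouridine	H2	base	U		D
i6A	N6-isopentenyladenosine	C5H8	base	A		i6A
m1I	1-methylinosine	CHN-1O	base	A		m1I
ac4C/f5Cm?	N4-acetylcytidine or 5-formyl-2'-O-methylcytidine	C2H2O	either	C	CH2	ac4C,f5Cm
ac4C	N4-acetylcytidine	C2H2O	base	C		ac4C
acp3U	3-(3-amino-3-carboxypropyl)uridine or -pseudouridine	C4H7NO2	base	U		acp3U,acp3Y
I	inosine	H-1N-1O	base	A		I
hm5Cm	2'-O-methyl-5-hydroxymethylcytidine	C2H4O	split	C	CH2	hm5Cm
hm5C	5-hydroxymethylcytidine	CH2O	base	C		hm5C
Q	queuosine	C7H10O2	base	G		Q
galQ/manQ	galactosyl- or mannosyl-queuosine	C13H20O7	base	G		galQ,manQ
mchm5U	5-(carboxyhydroxymethyl)uridine methyl ester	C3H4O3	base	U		mchm5U
mcm5U	5-methoxycarbonylmethyluridine	C3H4O2	base	U		mcm5U
mcm5Um	5-methoxycarbonylmethyl-2'-O-methyluridine	C4H6O2	split	U	CH2	mcm5Um
cm5U	5-carboxymethyluridine	C2H2O2	base	U		cm5U
yW	wybutosine	C11H15NO4	base	G		yW
m1acp3Y	1-methyl-3-(3-amino-3-carboxypropyl)pseudouridine	C5H9NO2	base	U		m1acp3Y
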