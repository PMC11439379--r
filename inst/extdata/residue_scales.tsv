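scale	residue	value
kyte_doolittle	A	1.8
kyte_doolittle	C	2.5
kyte_doolittle	D	-3.5
kyte_doolittle	E	-3.5
kyte_doolittle	F	2.8
kyte_doolittle	G	-0.4
kyte_doolittle	H	-3.2
kyte_doolittle	I	4.5
kyte_doolittle	K	-3.9
kyte_doolittle	L	3.8
kyte_doolittle	M	1.9
kyte_doolittle	N	-3.5
kyte_doolittle	P	-1.6
kyte_doolittle	Q	-3.5
kyte_doolittle	R	-4.5
kyte_doolittle	S	-0.8
kyte_doolittle	T	-0.7
kyte_doolittle	V	4.2
kyte_doolittle	W	-0.9
kyte_doolittle	Y	-1.3
hopp_woods	A	-0.5
hopp_woods	C	-1.0
hopp_woods	D	3.0
hopp_woods	E	3.0
hopp_woods	F	-2.5
hopp_woods	G	0.0
hopp_woods	H	-0.5
hopp_woods	I	-1.8
hopp_woods	K	3.0
hopp_woods	L	-1.8
hopp_woods	M	-1.3
hopp_woods	N	0.2
hopp_woods	P	0.0
hopp_woods	Q	0.2
hopp_woods	R	3.0
hopp_woods	S	0.3
hopp_woods	T	-0.4
hopp_woods	V	-1.5
hopp_woods	W	-3.4
hopp_woods	Y	-2.3
residue_mass_average	A	71.0788
residue_mass_average	C	103.1388
residue_mass_average	D	115.0886
residue_mass_average	E	129.1155
residue_mass_average	F	147.1766
residue_mass_average	G	57.0519
residue_mass_average	H	137.1411
residue_mass_average	I	113.1594
residue_mass_average	K	128.1741
residue_mass_average	L	113.1594
residue_mass_average	M	131.1926
residue_mass_average	N	114.1038
residue_mass_average	P	97.1167
residue_mass_average	Q	128.1307
residue_mass_average	R	156.1875
residue_mass_average	S	87.0782
residue_mass_average	T	101.1051
residue_mass_average	V	99.1326
residue_mass_average	W	186.2132
residue_mass_average	Y	163.176
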