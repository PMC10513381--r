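# Amino-acid bead registry: residue masses (amu), van der Waals diameters
# sigma (nm), bead charges (e) under the HPS, MOFF and Mpipi conventions,
# and normalized KR / Urry hydropathy scales (dimensionless).
code	name3	mass_amu	sigma_nm	charge_hps	charge_moff	charge_mpipi	lambda_kr	lambda_urry
A	ALA	71.0788	0.504	0	0	0	0.73	0.602941
R	ARG	156.1875	0.656	1	1	0.75	0	0.558824
N	ASN	114.1038	0.568	0	0	0	0.432	0.588235
D	ASP	115.0886	0.558	-1	-1	-0.75	0.378	0.294118
C	CYS	103.1388	0.548	0	0	0	0.595	0.647059
Q	GLN	128.1307	0.602	0	0	0	0.514	0.558824
E	GLU	129.1155	0.592	-1	-1	-0.75	0.459	0
G	GLY	57.0519	0.45	0	0	0	0.649	0.573529
H	HIS	137.1411	0.608	0.5	0.25	0.375	0.514	0.764706
I	ILE	113.1594	0.618	0	0	0	0.973	0.705882
L	LEU	113.1594	0.618	0	0	0	0.973	0.720588
K	LYS	128.1741	0.636	1	1	0.75	0.514	0.382353
M	MET	131.1926	0.618	0	0	0	0.838	0.676471
F	PHE	147.1766	0.636	0	0	0	1	0.823529
P	PRO	97.1167	0.556	0	0	0	1	0.758824
S	SER	87.0782	0.518	0	0	0	0.595	0.588235
T	THR	101.1051	0.562	0	0	0	0.676	0.588235
W	TRP	186.2132	0.678	0	0	0	0.946	1
Y	TYR	163.176	0.646	0	0	0	0.865	0.897059
V	VAL	99.1326	0.586	0	0	0	0.892	0.664706
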