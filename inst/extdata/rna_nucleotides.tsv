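# One-bead-per-nucleotide RNA registry (Mpipi convention): masses (amu),
# sigma (nm), scaled phosphate charge (e).
code	name3	mass_amu	sigma_nm	charge
A	RA	329.21	0.84	-0.75
C	RC	305.18	0.84	-0.75
G	RG	345.21	0.84	-0.75
U	RU	306.17	0.84	-0.75
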