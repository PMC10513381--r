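# One-bead-per-nucleotide DNA registry: nucleotide-residue masses (amu),
# excluded-volume diameter sigma (nm), phosphate charge (e).
code	name3	mass_amu	sigma_nm	charge
A	DA	313.21	0.8	-1
C	DC	289.18	0.8	-1
G	DG	329.21	0.8	-1
T	DT	304.2	0.8	-1
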