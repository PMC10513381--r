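34797cc10f26f6b1a373bedced79ae8a  aa_properties.tsv
a29634958aeeea865e688d222476d023  dna_nucleotides.tsv
1212dfe2dd8cd5cdea644c375c06d8a1  moff_epsilon_synthetic.tsv
969bd99b6cc52332d669027aae38bc49  mpipi_epsilon_synthetic.tsv
2e621c4920d9a4a4f3d48874f484b985  mpipi_sigma_synthetic.tsv
ad1fa95b9f5793dcfd9c6e459dc36ac6  mrg_bonded_synthetic.tsv
577e99cd7faa3c229e1a2ad71493c92c  rna_nucleotides.tsv
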