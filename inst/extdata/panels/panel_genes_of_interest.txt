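# genes_of_interest: 9 growth-regulator genes.
DENR
InR
MCTS1
Myc
Nelf-A
NELF-B
Nelf-E
pix
tor
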