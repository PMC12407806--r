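# translation_other: 61 further translation-associated genes
# (initiation/elongation/release factors and partners).
# Synthetic stand-in: membership reconstructed from standard nomenclature.
eIF1
eIF1A
eIF2alpha
eIF2beta
eIF2gamma
eIF2B-alpha
eIF2B-beta
eIF2B-gamma
eIF2B-delta
eIF2B-epsilon
eIF3a
eIF3b
eIF3c
eIF3d1
eIF3d2
eIF3e
eIF3f1
eIF3f2
eIF3g1
eIF3g2
eIF3h
eIF3i
eIF3j
eIF3k
eIF3l
eIF3m
eIF4A
eIF4AIII
eIF4B
eIF4E1
eIF4E3
eIF4E4
eIF4E5
eIF4E6
eIF4E7
eIF4EHP
eIF4G1
eIF4G2
eIF4H1
eIF5
eIF5A
eIF5B
eIF6
eEF1alpha1
eEF1alpha2
eEF1beta
eEF1gamma
eEF1delta
eEF2
eEF5
eRF1
eRF3
pAbp
Larp
Rbp2
Trip1
NAT1
Dhit
Gle1
Ns1
Ns2
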