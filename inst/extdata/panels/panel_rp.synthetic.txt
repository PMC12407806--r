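# RP_FBgg0000141: 94 ribosomal-protein genes (54 large + 40 small subunit).
# Synthetic stand-in: membership reconstructed from standard FlyBase
# ribosomal-protein nomenclature; the versioned FlyBase group is not
# fetched at runtime. Large subunit first, then small.
RpL3
RpL4
RpL5
RpL6
RpL7
RpL7A
RpL7-like
RpL8
RpL9
RpL10
RpL10Aa
RpL10Ab
RpL11
RpL12
RpL13
RpL13A
RpL14
RpL15
RpL17
RpL18
RpL18A
RpL19
RpL21
RpL22
RpL22-like
RpL23
RpL23A
RpL24
RpL24-like
RpL26
RpL27
RpL27A
RpL28
RpL29
RpL30
RpL31
RpL32
RpL34a
RpL34b
RpL35
RpL35A
RpL36
RpL36A
RpL37a
RpL37b
RpL38
RpL39
RpL40
RpL41
RpLP0
RpLP0-like
RpLP1
RpLP2
Rpp30
RpS2
RpS3
RpS3A
RpS4
RpS5a
RpS5b
RpS6
RpS7
RpS8
RpS9
RpS10a
RpS10b
RpS11
RpS12
RpS13
RpS14a
RpS14b
RpS15
RpS15Aa
RpS15Ab
RpS16
RpS17
RpS18
RpS19a
RpS19b
RpS20
RpS21
RpS23
RpS24
RpS25
RpS26
RpS27
RpS27A
RpS28a
RpS28b
RpS29
RpS30
RpS31
sta
Rack1
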