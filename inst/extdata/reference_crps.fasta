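>P82410 Momordica cochinchinensis trypsin inhibitor MCoTI-III
QRACPRILKKCRRDSDCPGECICKENGYCG
>P01075 Solanum tuberosum metallocarboxypeptidase inhibitor
HADPICNKPCKTHDDCSGAWFCQACWNSARTCGPY
>P81418 Phytolacca americana antimicrobial peptide
AGCIKNGGRCNASAGPPYCCSSYCFQIAGQSYGVCKNR
>P84781 Spinacia oleracea trypsin inhibitor
EDKCSPSGAICSGFGPPEQCCSGACVPHPILRIFVCQ
>P80403 Amaranthus hypochondriacus alpha-amylase inhibitor
CIPKWNRCGPKMDGVPCCEPYTCTSDYYGNCS
>Q5I2B2 Amaranthus retroflexus antimicrobial peptide
AGECVQGRCPSGMCCSQFGYCGRGPKYCGR
>Q07A30 Astragalus sinicus nodule-specific protein
TYSCGGHIDCKDFCKSEGYRGFKCTPKKTCTCFH
>Cmelo_chr7 Cucumis melo translated-genome homolog of citcol-8
RLGVCLLVGKPCMSDADCPSGCYCKPVPLLDIGYCGFL
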