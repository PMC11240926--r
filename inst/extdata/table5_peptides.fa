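>ACP1 KAB4_OLDAF
GLPVCGETCVGGTCNTPGCTCSWPVCTRD
>ACP2 CIRF_CHAPA
AIPCGESCVWIPCISAAIGCSCKNKVCYR
>ACP3 PSMA3_STAAN
MEFVAKLFKFFKDLLGKFLGNN
>ACP4 CYMEK_MELDN
GSIPCGESCVWIPCISSVVGCACKNKVCYKN
>ACP5 CYVNA_VIOIN
GIPVCGETCTLGTCYTAGCSCSWPVCTRN
>ACP6 CIRB_CHAPA
GVIPCGESCVFIPCISTLLGCSCKNKVCYRN
>ACP7 THN2_VISAL
KSCCPNTTGRNIYNTCRFGGGSREVCASLSGCKIISASTCPSYPDK
>ACP8 MYX_CRODR
YKQCHKKGGHCFPKEKICIPPSSDFGKMDCRWRWKCCKKGSG
>ACP9 CR12_RANCA
GLLGVLGSVAKHVLPHVVPVIAEHL
>ACP10 CYPLE_PSYLE
SVTPIVCGETCFGGTCNTPGCSCSWPICTK
>ACP11 UT114_PEA
EQQQQQQPQNRRFRE
>ACP12 TL11_SPIOL
FKGGGPYGQGVTRGQDLSGKDF
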