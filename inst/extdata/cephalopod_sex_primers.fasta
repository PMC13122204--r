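>Abandense_qPCR_auto_F
GGTGTTGTTCGCTCAGTTATC
>Abandense_qPCR_auto_R
GTGTTCATGTCGCCATCTTATC
>Abandense_qPCR_sex_F
GGCCGTCCTCTACTTGTAATG
>Abandense_qPCR_sex_R
AGTAGCTGTGTGGTTGAGAAG
>Obimaculoides_qPCR_auto_F
TTGTTTGGACCTTGGGCTTATAG
>Obimaculoides_qPCR_auto_R
CTGTCATGAACCCTGGTGTATTC
>Obimaculoides_qPCR_sex_F
CCTCACCACTGGATGCAATTAAG
>Obimaculoides_qPCR_sex_R
GCCAATCCGTCCAACCTATAC
>Sofficinalis_qPCR_auto_F
TTTGCCACTGTGTCCCTTTATAC
>Sofficinalis_qPCR_auto_R
ACACACACAGGCTGCTTATTG
>Sofficinalis_qPCR_sex_F
TTTCAACCCATCTGCGTCTATAG
>Sofficinalis_qPCR_sex_R
ACTCCTCTCGTTGCATGATTAC
>Eberryi_qPCR_auto_F
CTTTCGCCACGCCTGATATAC
>Eberryi_qPCR_auto_R
CAGCAGCTTCTTTCCCAGATAAG
>Eberryi_qPCR_sex_F
CTGCCCAGCGAATTGTTTATTG
>Eberryi_qPCR_sex_R
TCCGGCGTCTAGGGATTTAG
>Dpealeii_qPCR_auto_F
CACTTCAGCCCGATGGAATAAG
>Dpealeii_qPCR_auto_R
CTTTGTAAATGCCGCACCTATATC
>Dpealeii_qPCR_sex_F
GGAGTCTGAGGTCCGAGATATAG
>Dpealeii_qPCR_sex_R
GCCGAGACCACAAACAATAAC
>Illex_qPCR_auto_F
AAAACTCCCGACGTCTTGAA
>Illex_qPCR_auto_R
GGCCATCCTGGTAGACAAGA
>Illex_qPCR_sex_F
AATCACCCCAACCAGATGAA
>Illex_qPCR_sex_R
CTCCTGGACCTGGAATGAAA
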