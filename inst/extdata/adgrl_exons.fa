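>Adgrl2_exon9
CTTTTTGCTCCA
>Adgrl2_exon11a
CTCTTGTTCCCTTGGGACAGGGTCGCTCAACCATCATCCCCCTTTGTGTCTGAGGCCACTTTATCCCCTTCCAGTCTAACGCTTCGCAGAATCTCTCTGGCAGGGGAAAAATATTTGTTACAGGAGGAATTTTGGTTGTAGAGACGGCTGGAGGTGGCTTTGTCCCTCTGCTTCCGTCCTGAGGACCAGCTGCAGTGCTGCTCACGGGGCCTCGCTGGGAGGCACTGCTCGTGGTGGATATTGTGGTTTTGAACAGCTCAGCTGAAGAAGTTATTGTCACAGCTGTGGTAGGCA
>Adgrl2_exon11b
CTCTTGTTCCCTTGGGACAGGGTCGCTCAACCATCATCCCCCTTTGTGTCTGAGGCCACTTTATCCCCTTCCAGTCTAACGCTTCGCAGAATCTCT
>Adgrl2_exon14
CTTAAGGTAAGCCCTGCATGTCTTCTCTCGTTTTTGGAG
>Adgrl2_exon23
CCAGGTAAGTCCGTATTATAGTAGCCATCACAAACACGGTAATTA
>Adgrl2_exon24
TTGATAAATGGCTTATTATCTTCATAG
>Adgrl2_exon27a
CTGAGATAAAAGACGATTCAGACTGCTTCCTCACGGTGTCATTCCACATCCTTCTTATACGGCT
>Adgrl2_exon27b
CTTGGTTAAGGGTAGAAGTGCTATTGATGTCACCTGAGATAAAAGACGATTCAGACTGCTTCCTCACGGTGTCATTCCACATCCTTCTTATACGGCT
>Adgrl2_exon28
CTGGCGAGTTAAACGCAGGAGCTGAAGGGGCATTGCATACAACTGTTTCAGCGAGCAGGGTGTTATAGGGGTTGTTAGTGCCGTGGGGCCGGAGAAGAGGGTTTGTTAGTAGGTAATTGCCAGTCATCC
>Adgrl2_exon29a
CTCTAAATGATATAAATCTTGAAGATGGGCTCTCGGACCATGTGATGTCAGTC
>Adgrl2_exon29b
CTCTAAATGATATAAATCTTGAAGATGGGCTCTCGGACCATGTGATGTCAGTCCTGTAGTAATATATTAAGATTTATGTCAC
>Adgrl1_exon7a
TAGAAGTGGAGCAGAAAG
>Adgrl1_exon7b
AAGTGGAGCAGAAAG
>Adgrl3_exon30a
AGCCCTACAGAGAGACAA
>Adgrl3_exon30b
AGCCCTACAGAGAGACAAGTATGGGAGTAAAGCTAAACATTGCATATCAAAT
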