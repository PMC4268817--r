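TCTTTCCGGT
TTCATTATTA
GTTGTATTTC
TTCTTTCGTC
GCGTGACTTT
TGCGGTTACC
GCTAGCTCGT
TTCTCCCTGC
TTCTGTATTT
TCTTCCCCCT
TCTTTCGCAT
CGTTGTACTC
CCTCCTGCAC
CCCTATATTC
AACCCCTTCT
CCCCCCTGCC
GCCTCCCTCG
CATTCTTCGC
TGTCATGCTC
CTCCCCGTCT
CTTTTCGCCT
AATTTTTGGC
ACTTTTTTTG
CCTCTTCTCT
TTTTCCCCTT
TTTCTCAATA
TGTGCTGATT
CCCTTCTGTC
CTTCTTTATT
CTCTTACTGT
ACCCGTACCT
CCCCTCCCCT
GCCCCTTAAC
TAGTTCACTC
GTCTTCGTCT
CTCCTGTTTT
TTTTTGTCTC
TCTTCAGTCC
TCAACTCGTG
CTTATACCCT
CTGCCCTCTT
CTTCCTTTAC
TGGTTCATCG
TCTTTGCGCT
CACGTCTTCC
CTTTCCAAAT
TTTTTTGCCC
GCATTCTTTG
TCTATCGTCA
TCTACTAGCT
TGTCTATTTT
TCGTAACTTT
GGACTTGCCT
CTGCCTCATG
CCCCTGCCTA
GCTCCTGTTC
GTACTTTTTT
ACCGCCTTCA
TTGTGCTCTC
CACCCTTTTA
TATTCTCTGC
CTCTTGCTTT
CTCCTTCTCG
TTTTTGACTT
CTACTCTTAA
TTTTATACTT
TTTCATTCTT
CTCCTGTTAG
ACCTTCCGTC
TTTTCCGTTT
TCCATTTCTT
CCTTCCCTTG
ATACATCCCC
TCCCCTTACT
CCGTTCCTTC
TTCTCCTTAT
CAACTTCTCC
ACTCTCCGCG
CTGCCCGCGT
TTTCTTGTTC
TTTTCCCCCT
TTTGCCCTTA
CTCTTTTATC
TCCGTCTACG
GCGGGTCGTT
CTTGCCCTCC
CCTTCTTCGA
TTATTCTCGC
TTTTTACTCT
TTCTCGTCCC
GATTCTTTTC
TTTGCTTTCT
GTTGGTATGT
TCGTTGCTTT
TTGCCTTGCT
CCACATTTCT
CAGGTTCTCA
TCACTTTCTC
TCTTCGTTCC
CATTATTCTT
AGCGTACTCT
CTTTCGGTTC
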