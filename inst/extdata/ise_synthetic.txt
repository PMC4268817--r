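GGTGAT
ACTATT
GCGAGA
TGTGAT
CGAACG
GTCGGT
GCTCGC
AAACCC
CGCCCG
AAACTC
TGTTAA
GATTTC
AACCGG
TAAGCA
CCAATG
ATACTC
CCCCCA
CAGAGA
TCATCG
GGCGGG
CCAACG
CGAGTG
ATTGGG
TCGACC
ATAGTG
TGCGGA
GCCGTG
CTCTGA
GTACAA
GTCGGA
TGGAGA
GTCACA
CCGAGA
GTAGGT
CGGTCA
ACTGAG
CCCATA
ATGTTA
ATGTGT
TACACT
TACGTG
CCGAAA
ATCCAG
GATCCT
GCTATC
GAGGCA
GTGTAC
CGCCTG
TGCTGG
GACTGG
TTTATG
TCGATT
CCCTGC
AGCTAT
CACGCT
TCCGTG
CGTCAT
CCCGAC
GAAGTT
TGCATC
AACTAA
TTCTAG
TCCGCC
TATTGG
AGGCAC
GGGTCA
CACCGG
ACCGGA
CAACAA
ACAGTC
TCGTCC
ATGATG
CGTCCG
TCTGAT
AACACG
TTGAAC
TTCAAT
GGAACG
CGCAGG
AGCCCT
GGGGGT
GGTGTA
AAACGG
AGCGGT
AACAGT
AACGAG
TCAACG
TGGGAA
ATGCCC
GGCTTT
AGTACG
TATGTC
TCAGAA
ATGCAA
TGCGGC
TGGTGG
ATGTAT
GTTAAT
CCTAGC
ACAGGC
GCAGCA
AGCATT
TAACGT
GCCCGG
CTAGCC
TAACGA
GAGACG
CTGGAA
AAGTCA
TGGTCG
CCCGAG
CAGTCT
TCATAT
AGTAAG
TCGGAC
CGAACT
ACAGAT
CGTCGG
AATTTG
ACCCTC
GATACT
GCTGGT
AAGCGC
ATTGCT
TACTAT
TTGGCA
AGGGCC
TAAAGC
TGAGTT
GACGGG
GGACTC
GGAGTG
AAGTAC
ACGGAG
ACTTGC
GAATTA
CGAAAC
AAGTTC
CAAATA
ACACCA
CACCCC
GTACTT
CGAGGG
CTGAAT
GCCAGA
TGACTA
GTAAAT
TGAACA
GGGTGA
AGTTGA
GAAAGA
CCACCG
CTAGTG
AGGTAT
TTGTCG
CTCATT
ACTGTC
GAACGG
TTTGCT
GTTGAG
GTTAGA
TCTCTA
GGCAAT
AGGTTA
AGTAGT
TTTACT
TAGCGG
GAGCAC
CCTCCC
TACATG
GGAACA
ACGTGG
TGGCAA
ATGTGA
AAAACA
CCTGGT
GGAGCT
TGTCCT
AGCCCG
GCTTCG
GATGGG
AAGGTA
GCAGCG
GAACCT
GTGGTC
AGCTTG
AGTATA
CTGTTT
TCGAAT
GGATCC
GGTGGG
CCGGCC
CGTCCC
ACGCTA
TACCAA
GAGACC
CGATCG
TCACAT
CTCCAG
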