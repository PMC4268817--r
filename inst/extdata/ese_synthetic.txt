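TGGAAC
GAGGAA
TGGTAG
GCCATG
AGACCG
AAGAAA
ATGAGA
AAAAAT
CAGGAA
GGCTCG
GAGGCG
AAGGAA
CTAAGA
AACAGC
AAGAGG
CAAGTC
AGCTAA
GGAGAG
GAGCGG
GGACTG
CAGGGC
CAGAGG
GTGAAG
GAGTAA
AAGATG
GAAGGA
AAGATT
TAAGAT
AGAATA
AGAGCC
AAAAAG
TAAAGA
GATAGG
GGGAAG
GGGGGG
GTAGGA
TAAGGC
ACGGAA
GGGGAT
AGAGAG
GAAGAC
GATTAA
AAAGAT
TTGCAG
AGAGAA
AGGGGG
AAGGAC
ACGAAA
GGCGAG
GTGAGC
CAGGGA
CGGGGG
GAAGAA
CCAAAG
AAAGGG
AAAAAA
CAGCTG
AGAGCT
AGGGAG
ATCTCA
AGAGTA
GGGTGG
GTGCGG
GGATAA
GATTGC
GGGAGA
GGGAGG
AGAGGA
AGGTGT
AAATAG
AAAGAG
TGAGTC
AAGGGA
GAGGAG
ACAATG
ATAGAA
GAAAGG
TGAGGG
AAGGAG
AACGTG
GGCATA
ACAGAG
GGGCGA
AGATTA
AGTGGA
ACACGA
AGGAGC
AAAGAA
TAAGCG
AAGAGA
TACGTA
GAAGTC
GGAAGG
GAATGG
CACGAT
GTAAAA
GAAAAT
TAATGT
GCAGGC
GAGCGC
GAGAGC
GTAGAA
TACAAG
GGGCGG
GAGCAA
GAGTGG
CAAAAC
CGTGAT
GGAAAG
GAAAAA
AAGCAG
ACGATA
CAGAGT
ATAAAC
AGCATA
GGCTAC
GACAGA
ATGAAA
TGAAGT
CAAGGT
GATGAA
CAGAAT
AGAATC
GGGGCG
GGGCTC
AGCCAA
GGATGA
GCGAAA
AAACCG
CAAGAG
GAAGAG
CAAGGA
GAGAAC
AGGAAA
AGAACG
GAAAAG
CGCACA
AGAGAC
GGAGGG
ACAAGG
AGACGA
ATAAGA
ATGAAG
AGATGA
GGTGTG
GAGAGA
AGCGAG
AAGTGT
GAGATG
CAAAGA
GGTCCA
TAGAGT
GCAAGA
ATTTGG
AAATGT
GGGGGC
AGGAAG
TTGCAC
AAGAAG
AAAAGG
AGGGCG
GGGGAA
ACGGGC
GAGGTG
GGGACG
GGACGC
AAAGGA
ACCAAG
GAGCGT
AGAATG
TAATGG
GAGTGA
AGAACA
CCGAGG
CCTGGA
GAGGGC
GATCGA
GTGAAA
GGAGGA
AAGGGC
AGTGAA
GAGATC
GACTAG
GAAAAC
ACAAGT
AATAGC
GGGGCA
CAAAAA
GTGAAT
AGCTGA
GGCGAA
GACGGA
GACGAC
CGAAGG
ATTGAA
TTGAAA
AAATGC
GACAAA
GGAGAA
AGGGAT
CAGAAG
TAGGAA
GGAGAT
GACATT
GGATGG
TGCTCC
AGAAAA
CGCGGA
CAGATG
GGGCAG
GAAATG
AGGGAA
TGCGGG
AGAAAG
AGCGTA
GCGACG
AATAAA
TGTCGT
AAATGG
GAATAA
GCGGGG
AACAAT
GGGAAA
GGAGGC
CTGGGT
AGCAAG
GATTCA
GGTTAT
AAGCGA
ATGAGG
GAATCA
TGGGAT
GGAGAC
ACGGGA
TCGAGG
AGTGTG
GGTGGC
GCGAGC
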