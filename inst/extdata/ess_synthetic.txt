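CCGCCT
CTCGCC
TTTCTT
TCTCGG
GCTCTC
TCTTCT
TATTCT
TCCTAT
TTACGA
GAACTG
CCTCTT
CTCCCG
CATTAT
TTCGTT
CTTTCC
TCGGAG
CTTCTA
GCCTTC
TAGTGC
TCCGTT
CTCTGC
CTTGTC
CCCTTT
ATCTTG
CCAATA
CGTTTA
TACTCA
TCACCC
CTGTCC
TTTTTC
TTTTCT
TTGCTT
TATGGG
TGTGCC
CTCTAC
CTGGTC
TTTAGT
TTTCAC
TTTTGC
TACTTT
TTTACA
TCCTCC
ATTCAG
ACCGTC
TCCCCC
CCTTCT
TCCATA
TCAATT
CCTGTC
TGTATT
TTACCC
TCCGAT
CCTTAT
TTACTC
GCAGTC
TTCTTT
TAGATT
CCACCC
ATTCTT
CCCTTA
TACATT
TATACT
TCTATC
ATTTCC
ATTCTA
CATCTA
TCCCTT
CTCGCT
ATCTCG
TACTCT
TCCACC
TTTTAC
ACTCGC
CATCCC
TTCTTG
CCCCTT
TTTCCC
GGGCCG
ATCCGC
TTTGCG
TGTCTT
TCTCAT
ATGCTG
CCGCCC
TTCCTC
CTCATA
GTTCCA
TCATCC
CTTTTC
CTCTTT
CCTTGT
TTCATC
CTTGCT
TTCTTC
CTCATC
CTCTCT
CCCTCC
AACTCT
TCCTGT
CCCCTG
CTATCT
TACCTT
TCGACG
TCTATT
CATTCT
TCTTTG
GCTCGA
ACGTAC
CTACCT
TACGCC
CGTTCT
TTATCT
CCTTCG
TTTTCC
TCTCTT
TGTTCC
CATCTT
AGTGTA
TTCCTG
CGTCCA
TTATTT
TATCTC
TTTTAT
TATGCC
ACCTTT
GTCTGA
ATTTGT
CTATTT
TTTTAA
TTCTCT
TTTCCT
TCTTTT
CCTTTC
CTCCTT
CTCCAC
TGCTCT
TCTTTC
CTAACT
CCCTAT
TCATTT
CTCTCA
CTTTTT
CTCGTA
CATCCA
TGTCCC
ATCCCC
TTTCCG
TCTGTA
GTTCAC
TCCTCA
TCCCCG
TGGTAT
TTCATT
TTAGTC
GCTACG
TCCTTC
ATCCCT
ACTCAG
CTTATT
ATTCTC
GGGTCC
TTTCTC
TATCGG
CTTTGC
TGACTC
GTCATT
TTCGTC
TGCTGC
TCTGTT
CCCCCT
TACCTG
TACCCT
CTTTTA
CCTCGA
ACTATC
CTAGCT
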