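>synthetic_SOCS1_exon2 1766bp synthetic stand-in; ORF at 705..1340; 761bp product of the printed primer pair
GTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAA
CCCTCCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTAT
CGTATTCCCAATTAACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAG
GAACAAGCGTTAGAGGCATTCAAGCCTGAAGCAGGAGCATCCTTCTTACATAACCAGCTT
GGGATTGTATATTACACTGAGAAGTAGGGTCAACGTGCTGAGTTGGGAAGGATAAAAGGT
ATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTGACATACAATTAATCCG
CATACCATAGTGTTAGCCGTGATTGACAATGCCCAGGGTCCCATGTGAGGATCACGTGTC
CCACATACCCTGTTAGCGTTTTGTGTCCAGCGACCGATTTTCAACGTCAGTAGCGTGACG
GTTTTTCTAAGACAAGGCTTGCTTACTTCATGGCAAATACCGGTTGCAGGCAACGCTCTG
CGGAGCTCGGCAATTCACAAAGCACAGACAAGCTTAAGAACACTGATTAGTTAGAGAAAA
CTTTACTTCGTCGTCCCGCCATTGTTCGATAGTGCAACTACCCTCGCAGAGACGTGCATT
TAATTCATGCCGGGGAATTACCTGTTATTCCACCCCCGGACGCTATGGAGTTGAACTTTA
CTGGGCACAGCTGGCCTGGCGCCATGCCGCCGAGTGATGTTTACTCATATCTCCCGACGA
AGCAGGTTACGACGACTAGTCAGAGACTCATGCCAACCTCCTACAGTAATGTCCCACGAC
CAGGTAGAGAGTGGTCCGAGAAAAGACAGGACGAATCCGGTAACGCCAGTTCCCAAATAC
TTTTCAGGCCTCATCTTAATTTTGCCGCCAAATCCCACAGATCCAAAAACTGTCTGACAT
GGAAACAGGTACAGCACGTTCCAAACCGGTGGGGACATCGGCGAAGAGTAATGAGGCCGA
TCAATCTGTATAACCACCCCGATGCTCGTGTAAGCATTAGTATAAACGGAGCCCGGACTT
ACTTTAGCGGCCGTCTCGGTCGGCAAAGTGTAGCGTGCAACCAAGCGCGACATAAAATGC
CCCGTACCAGCTTTCGGCTTCATTCCCGAGCAAAGACGGGGGTTGTGTTACATACCTCAG
TTACCGCCAGAGTGAAGGGAGCTGAAGATGTGGCTGACGTCCGCTCAGTCCCAGAGCAAG
CCGCGCTACCCACATTCGTATTTAGAAACAAGGGAGGTTGGCGTACTTTCCCCCTGACTT
GTATCACCACCGTTCCCTAAGGCGGGCGTGGAGTAAAAAAGACTATTCATATTTGCGATA
AAGATGGATGCACATCGACATAAAGTGTGGGGGATCGATGTCGTACACCCTACTTGCCTG
GAACCATGTGGCCAGGCTACCAAGCGGAGTTCAGGGGCGCCGGAGCTGTACTAACGAATT
GCAACACTAGAAAGTCGGTCTACCTCCACAAAGCTAATTGGATTTGAATACAATGCGGCA
TTGCGCTAGGGGTTCGCCAGAAATCGATCAGGCCAATTTTCGTTCCGTACACGCTCGCCG
ATCCGTTTACTTGTTCGTTGTTCTATTAAGCCGAGCCAAAGGGTTACGTTACTTGACCGG
TCGCGCTGCTTGTGATCCCTCTGTGGGAGCCAGGAATAGCTTACGATACTCCCATGCGAT
GGAACACGCTGATCGCAGGTATAGGT
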