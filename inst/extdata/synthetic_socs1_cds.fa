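>synthetic_SOCS1_CDS 636bp synthetic stand-in (not the real transcript)
ATGGAGTTGAACTTTACTGGGCACAGCTGGCCTGGCGCCATGCCGCCGAGTGATGTTTAC
TCATATCTCCCGACGAAGCAGGTTACGACGACTAGTCAGAGACTCATGCCAACCTCCTAC
AGTAATGTCCCACGACCAGGTAGAGAGTGGTCCGAGAAAAGACAGGACGAATCCGGTAAC
GCCAGTTCCCAAATACTTTTCAGGCCTCATCTTAATTTTGCCGCCAAATCCCACAGATCC
AAAAACTGTCTGACATGGAAACAGGTACAGCACGTTCCAAACCGGTGGGGACATCGGCGA
AGAGTAATGAGGCCGATCAATCTGTATAACCACCCCGATGCTCGTGTAAGCATTAGTATA
AACGGAGCCCGGACTTACTTTAGCGGCCGTCTCGGTCGGCAAAGTGTAGCGTGCAACCAA
GCGCGACATAAAATGCCCCGTACCAGCTTTCGGCTTCATTCCCGAGCAAAGACGGGGGTT
GTGTTACATACCTCAGTTACCGCCAGAGTGAAGGGAGCTGAAGATGTGGCTGACGTCCGC
TCAGTCCCAGAGCAAGCCGCGCTACCCACATTCGTATTTAGAAACAAGGGAGGTTGGCGT
ACTTTCCCCCTGACTTGTATCACCACCGTTCCCTAA
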