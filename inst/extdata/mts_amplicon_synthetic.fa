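>mts_amplicon_synthetic window_start=650 window_end=655 wt=TTTCTG
GTACTCGACTAAATATTATCGGCTTCACTGGTTCCGCCACCTCGCTGCATGCGGACGTTG
TACGCTGGACCAAGGTAAATCCATCAGAACACGTGGTTCCGGAACTACACCCTCGATGGC
GATTAAGGAACGTTTACAGGACAACTAGCACAAAACGCTGGAGCGGACAAGGAACCTCAA
TTCAATCGTACGATTAGAGAATTAGGCCCGGAAGAACGGTTGACTTATTAAAAGCGGTGC
CCTGGCGTTGAAGACTTCCAGTCTTTTCAGATTGAGAGCTGAGGCGCATCAGAGTGCACG
AGAATTTGACTCACCTCAGACGGGTTATGGGGCGTGTGCTGAAGATCAGATAACAATGAG
ATCTTGCCCTCTGGGCCATACAGTCTCTGCCGGCTAATGTCGACTGCGGATAGATTTACG
TGGTCGAACGTTCCAAGCCTTTCCCGGCATAGACGAAGTAAGTGTTACTAGCTCTTTCTG
CAGGTGACATAGCCATGTTTGACCCTTATCATTGAAGTTCGCGGTTTAGGCCGACGACAT
CCATTGGAATGCGGCCAATCATGCGGGAGCGTTTTGCCCCGGCTCCTGGGGCACTGGAAT
GAATAATATGCCGCTGTTCGCTTGCCTTCCTGTAGGTAGGTTAGCCTGTTTTCTGGCATG
ATGGTCGCTCGTGCGAGAGATGCGCCATGAGGACATCTGGCCTCCTAAGTCCTGACATAG
CCAGGTGGATGTCCCGGCGCTCAAATGGTGGAATAGGGTTCCACCTTCGCGACCGTACTT
ACAACTCCCGTTAGTCCACAGCCGTACCTAATGGTCGTGCTCAGGCAAGCGTGTTTATCC
CAATCTACTCCCACCTCCTAAATCTGGTAAAGTTAGCTATAGCTAAGAAATTGCCGACCA
GATAAGGCCTTCAGAAAACGAAGGATCGTATTAAAGAGACCATGTACCCGGAATCGGCCA
GCATCCCTTTATAGCGACCAGTTTTTACCGTCACCCACTAGCCTTGCCCACACGATTCGG
TATGTCTAAGGTGGGTCCACGGCCGAATATAATTGTCGCGATGACTAACAACCTTTAGCG
GCGGTAGGCTGTCAAGCTTAAATCTGTCCGGACCTAAGAGAAGAGCCTTCACGGGTACCG
GTTAGGGTAATCGTGAGATCAGGTGAATCTTTAAGGCTCCACGCCCACCTGTAACTCGGA
CGGTGCGAGACCTTAATACAATAATGACTTCAAATGCGTAGAGGGATCTGGGAACAGCTG
ATCGCGTTATACAGTCACGAGAATATGGCTTCACTACTTGTCTGAGTTCATTGGAGCTAC
AAACCCATGTGTCGCGACGGCACCACTCAAACCAGGTCGTTAATTGGCATGCCCTAGGAG
AAACGCGGCAGCTCCTTC
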