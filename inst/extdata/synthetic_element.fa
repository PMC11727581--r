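>synthetic_element synthetic 1 kb element (not a real LINE1 consensus)
GTCCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCCATGCTTAATT
GCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCTGTTGATTTAAGAAGAATCAC
ACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTGACCCGCAGCTCTCCTGCGGCGAGTTATGGC
TGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGTGCGTCCCCTCCCCCGAGATCGCTATTGTAACTACGCGACT
CTGGCTTTAACCGTTGTGTCGTATGCTGCGCGAGAGGAAAAGATTGGGCTGTAGCGGGAGCCATAATGCTGGGCTACCTC
CACACCAACGGCACAGCTAGGACGGAACAATTTTAACACGTTCTATGAACAGGAGTTGCTGTGATCGGAGCTAAAGTCAC
CGTACCCTAGAGGTCGCGACCTTGTGGCTCACCCCGCCCAACGGTGCATCTACTCGATGTCGTCGATTTTTACATGACTG
AGCGGAGCTGCGGCTGTCCGGGTGCCTCTGCTGCGCTGGTGGACACTGAAGAATCTAGTGTTCCGTCTCGTCCTCATATA
TGCAAGGCCCAATGTCAGCGCAACTCGGCGTGGTAAGACTACGACTTATTAGTAACAACAGGATTGTGAAACTTTAGGAA
GTTCTTATTTCAAAGCTGGTCTGAGACGAAATAGTCCTACCTTATCAAGAGTACTATAACGCGGTGATAAAGGGAGTTGC
ATTTGATGGACAGATAAGTGTGACACCGTTATTCTCAGGGTCCTCTGTTAAAAGGCAATGCGTATTTAGTCTTAGGTATG
AAGGCTTGTGAGGAGGGTCCTGGTGACATGTCTCATAACGCAAGAACGTTGATTCCACACGACAACGCTGCAGTCCGCGC
CGCGGGAACATAGGCTTGTTTTATAATGACGGCTCGTGCG
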