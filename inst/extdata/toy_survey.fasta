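>NIRK0001
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAA
ACCAGAACTAGATGACTAGTACCGAAGGCAAAGATGTACTTAATATTCGCGCGTACATAC
CTGTATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCT
GAGACCACAGAACAATGTTCAAGGAGCTAATGTATATCTTGTGAAACAATCTGTAACACT
CACGGATAATCGGTATAGATCAAGAAAAGTCTTAGGGGGACCCGTCATATGTCCGGACTC
TAGGCTCAGCTGGGAGCGCGTTAGTGTCGTGATGTGGCTAGGTTTCTAATAGCGCAAGCA
GACGTGCCGCGCTCTGACAACCACCTTGATTGTTTGGATCCATTGAAATCGTGAAGTTCC
TCTGAATGGGTCACGTCGGCGATTTGTGGG
>NIRK0002
CAATGTATACCGAGTACTCCCTCCTAAGGAAATTTTTTGCTTGGATTTTGTAATTGACAA
ACCAGAACTAGATGACCACTATCGAAGGCAAAGATGTACTTCATATTCGCGCGTACATAC
CTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCT
GACACCACAGAACAATGTTCAAGGAGCTTATGTATATCCTGTGAAACAATCTGTACCACT
CACTGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATGTCCGGACTC
TAGGATCAGCTGGGAGCGCGTTAGTGTCGTGATGTGGCTAGGTTTCTAATAGCGCAAGCG
GACGTGCCGCACTCTGACAACCACGTTGATTGTTTGGATCAATTGAAATCGTGAAGTTCC
TCTGAATGGGTCGCGTCGGCGATTTGTGGG
>NIRK0003
ACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACCAGTATCGAAGGC
AAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGTTTGCCAGCGAAGCT
CGCCAGCCGGACCACGAACATACAGTATTCTGACACCTCAGAACAATGTTCAAGGAGCTT
ATGTATATCTTGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAAAG
CCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGGGAGCGCGTTAGCGTCG
TGATGTGGCTAGGTTTCTAATAGCGCAAGCGGACGTGCCGGACTCTGACAACCACGTTGA
TTGTTTGGATCCATTGAAATCGTGAAGTTCCTCTGAATGGGTCACGTCGGC
>NIRK0004
CTCTATGCCTCCTTCGAATTTCTAACTGCAACCGTATACTCCAGTGCCTGGTATAATGGA
TCCAGCAGACCATTGAGTGGCGACCGGCAATCACATTTTGTTTGCAGTTACGCCTGAGGG
AAGGGTATCTCGCACAAGAATGTCGGGAGGTGCAGCACAGAGCGCGAAGTTACAGTATCG
TCGGACGCGTCAGCTTAACAGCTGCGCACCCAAGAACTTAAAGTAGGACGAGGTGAACAC
TAATGACACAGACGTCTATTTCATTGTTGCCTGGCGCAGACGCTTGTGACAAATCCATCC
AAGCACTGATAACAGTCAAGGCTGAGCAAGGGGTTGTCCCGGGCAAAAACGAGTTTACCC
GAAACGTCCAGGCGATCCAC
>NIRK0005
CTCTCTGCCTACTTCGAATTTCTAACTGCAACCGTATACTCAAGTGCCTGGTATAATGGA
TCCAGCCGACCATTGAGTGGCGACCGGCAATCACATTTTGTTTGCAGTTACGCCTGAGCG
AAGGGTATCTCGCACAAGAATGTCGGGAGGTGCAGCACAGAGCGCGAAGTTACAGTATCG
TCGGACGCGTCAGCTTAACAGATGCGCACCCAAGAACTAAAAGTTGGACGTGGTGAACAC
TAATGACCCAGACGTCTATTTCATTGTTGCCTGGCGCAGACGCTTGTGACCAATCCATCC
AAGCACTGATATCAGTCAAGGCTGAGCAAGGGGTTGTCCCGGGCAAAAACGAGATTACCC
GAAATGTCTAGGCGATCCAC
>NIRK0006
TTATTTACGCTCAAAGCCTGGCAATGCATGCGGGACAAGTAACTATCCATTTCACGGTCG
CCCTACGTTTTACTTCAAATCTACATATCTTAAAGGGATACCGGACTAGATCAGATTCGT
AACTTGAACTAGTTCTCCGTTACAACCGGAAAGTAGTGTCGTCAGTGTACCCGGATGGGA
GTGCACTAGACGGAGGTTGCTTGGGTGATTTATAACTAATGGAATAGTTCCAACCCCGCT
GGCATACCGACGGCAGTCTCCTCGCCCGGGATCAGAACGCGTCGACGCGTCGTTTAAATT
AACTAACCGACAGGGGCTCCAATTGTTGCACGAGAGAAGTCTATCTAGGCCTGAACAGCC
GTGTTGTGTCAATAAGAAAGACTGCCTACTAAAAGTCACTGTTTCATGTACCAGCTTAGT
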