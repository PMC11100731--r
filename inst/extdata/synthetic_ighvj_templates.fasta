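>IGHV1-S*01
AGCTCTCCTGCGGTACTGAGCTTTAGGTCTGCGAATTAGGATGACCCGGATGAAAACGCTCATCCACCCGAAAGTTTCGTAGGTGCGCGTTTGCAGAAAAACGTGACAAGGAGTATATGGGCGCGAATGCCACTAATCAATAGCAGACCCCGGCCTACAAGTTAGTTACTTCCCCGGGAGAGCACTATGAACCATTCAGTAAACTTTGTTCCGGAAATAGTTTGTTAAGTATCCGCTCAA
>IGHV2-S*01
GGGATATACAATGGTTAAGGCGACTATGGCGAACCATAGGAGATAAAGTGGGCACGTGGTAGGGGGAAATCCGGAAGGCTACCTGGGTCGAGTAATACGTAATTGAAACACATCATTTTGCTGCGCTCCTCAGTATAGGCTACAAACACCCATGCGGGACGGCAAGTTTCCTGTTATACTAGCCTTTCCCCTAATGTCTGTCAGCGATATCAGACCTCTTAGCTGTTGCTGGCTTGCGAG
>IGHV3-S*01
ACCCTAGTACAAACGCATTACCAACATAGAAAGACAGATGACGACCTGTTGCCAGGCACGAGAAAGGTTAACCTTTTCCTGATCCTAGAGGCGCACCACCTATATGGATATTGAATGGCTTCCCTAGAGCCCCATAGACAGACCTAGTAGATAGGTCCGACATCTTACTCGATTTACTCCTAGAGTGTCTCTCGGCCCGCTTGGACTTTGATTGTCTTGTGTCGGGGCCCGGCCACAACT
>IGHV4-S*01
ACTGCCGCTCCTCACCCCCTAGAAGACTGGCGGTTTACCTCAATCACTAGAAACAGACCGAGGGATACCGCGAACGTATAGTCTAGTCGGGTGAGTGTCCGGGCGAAGAGAAGGCCTTACTTATAAAATGTCCTCTACGATACGGCATGATTTCCAAAGCGGGGAGAATGCCCGGCCATCGTGTCGGTTCCAATCTCTAACCAGGCTACGGCTAAGGCTAAAAGCCCCGTTGCCGATTTA
>IGHV5-S*01
AGGATTAATATCTGCACATTTATTGCTGATTTGCGCGACATGTAATCGTCGGCGTTGTGGCAGCGATACGCTCAAACCGGAGACGTCCTGAGTGCGTATCGGAGACCGCATGACTAACTTAATTCCCCTGTGATATCTAGATGCTTCCGGCGGGCTGTCCGCACGTCACGATTTCCTTCATGGAGATGGAAAGACCGTCGTGCGAGCATAAAGCCTGTAGTTGCTCGTTATACCCTGCCC
>IGHV6-S*01
ACGGGAAGGGCGGTCTTCAACATCATCGGCCGCTCAGTCTTTTTAGTGGAAATGAGTAGCAGCAGGACGTGGGGCTGACCATTAACTACCCGATTACCGCATTGACTTATAAGCACATCCTATTTTTCATTTGAGAGTGCAACATTTCCAGTTTGGAACCGCGGGTTTGGCTCCGTCCTTCGGGGCACAACACGCTAGTTAGATTGACATCGCTTAGCTACACTCGGCGACATCAGCTAC
>IGHV7-S*01
GAGTTCTCATGTTCTCAATAATCGTTAATTACTATGATCAAAACTCATGCTAGTTTCACCGTGCATTATCGCAGGGTCCTCCTACACTGGGTCTATGGTGACTTTCCGCTGGTCCAGTACACCGGAACCCAACAAAGACCAGTGATGTTCACAGTTCGCCCGAAACGTTGCCCTGGGCAATGAGCGGATCTACTCATAACTTAGGTTTCAGGAGAGCCACTACCAAAGGGACATCATCAT
>IGHV8-S*01
ATAGAAGAAGCCCGTTAGAACTTGCTCAACTCGCGGCACGTTCTGTTATGTGGGGAATAGCGGGTTGTTATATTCGAAATCCGGGCAAGTCCGCGAATAATCCATGGACCTCACGCTAAAGCTCTCAGGACACCAATGATTACAAACTCAATATCTGCGTCGATCTATCGTACGGGACTACTAGACCGTGAAGATCACTAGTCGAATGACGGCATACAGTGCATAGGTCATGTCGCGTGA
>IGHV9-S*01
GGTGACCAGGGGACAGTGACTACCTGCCACCTGGTCTAGCGCTTCCCCGCCAATAGAGGAACCAAGGCCTCCTATACCCCAGTGCTGCTCTCACTCACTAAGCGATACTAATACTATAAACCCAAAGATCTTTTACGATGACGTAAAGGACCCGTACATTTGAGACGCCAACTCCTAGACCCATATACATAGTCTTTGAATCCAGTTAACTCTCCCCAAATCAGACAACAGACAGCAACT
>IGHV10-S*01
TTTAATACGGCAGGTGTTCCAAGCGAGAGACGAGTGTTTCCTGCCTCCGCGAGCCTTGCGAATGATTTACGTAGTGTTTAACGTAAAGGTACCAATGGACATCGACTTGAAGCCGACGATAAGTACGCCGTCGACAGGTCGTCATTTTTGCGACAGCTGCCACAGAAATGTTAATCAAGCTGGGTGGTGTCAGTGTTGCCGAAAACTCCACATGTTCTATAATGATAAGGAATCATCATC
>IGHV11-S*01
GACCATACACGTCTACGCAGGCACAGCATTACGATGACTGCAGTAGGTAAGGATCTTTGAGCCAATGAGGTGGGCGCGAGTTTCTAGAACGGACGTGCCGGTGAATCCTTAGGTCCACAACAAGCGACTTTGCGGACATCACTACATTAAGTGAGTTTGTCGCGTGGAATTCACGAGCTATTTAGCTATCCGCTTGATGCTTCTATCAGTTTAATGGGATCCTAAATCAATCGAGTGTAT
>IGHV12-S*01
GACCCAACGGCACACTCCTCGCGAACTAGGTTTGTACGGCAAAATATATCGCGTGCGCAGCAATCAATACCCGAGCGAGGCAAGTCGAAGCCCTACACGAGGTAATAAGCCCGCTCGCACCGAACGCGCGATTACCGGGTCGCCAAGGCTCATGGGTTTCCGGGTGGCTCCATCTTCAGAAGAGCTTAGGAATGTGTTCAGCACGAACGAGCGTATACTCCCGGTTGAGCAATATATAGC
>IGHJ1-S*01
GAACCATTAAAGTTGCATCGTCGCGGCCCACACGGTTGCAGGCTG
>IGHJ2-S*01
ACACCCGCGTGGTTCTTTCCATGGTCGGACGATTCATAGAGCCCA
>IGHJ3-S*01
CACTGGTATTCCCTGGTGCTAGTGTATAGACAGTAGGTTGTCTGG
>IGHJ4-S*01
TTTCGCCGAGATGAGTCCGTTGAACGTAATTCAAGAATCGATTCT
>IGHJ5-S*01
ATGTGATGTTGAATCGTTTCGGTGTTAACACTAGCTCCCAGAGAA
>IGHJ6-S*01
GACACCTCGCATACGGGCTCACCTCATATTACATTTAGATGCTTA
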