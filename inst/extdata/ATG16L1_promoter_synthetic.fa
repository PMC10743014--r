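>ATG16L1_promoter_synthetic (randomly generated fragment; reference alleles at panel offsets)
CGAGGAAACGGGGCCGATTCATGACTGCACCGACCTTAGGGCCCTTACCTTTTTTTAGTTAGGCAGGTGC
TTTACTCTACGAGCTATACGATGTGGTGTACCTATAATACACACGTCTATTCCGACTAGTAAATGGTAGG
ACGCGCGTTGGAACGGACACTTCGCCGGACTCTTCGAATCGGGGAGGGGGAGATGGCCGATATTTATGAC
CAAGATTCGAGAAAGTTGAGTGGTTCGACCCTTTCTTAGGTACTCCCCCGAGAAAAATCAGCAAAATGGC
ACAGCCAGGGTGACAAACCTAGGCCTCGCGGAGGACGAGAGGTCTCGTCCATCTATGTTGCACTGATGAG
ACGGGATCGACATTAAGTAAGCCCCGCATAGTCTAGCTACTTCCGATTGTGGTGCAAGGACTCCAGGCCT
ATCGTGAACCTATTCACGCATGCCTTTGAACGTGGCCTTTGCATCTAATTTGTTGACGCGCATCGTCTGG
GAACACGAGATGTTAGATCTGTTATCAGTTTAAATTCACTGACTGAGCGGTTGCGGTCACTGGCAGCACA
TCCTCCCCCTTATTAAATGCGGACCTTCCAATCTTCATCATATCTCTGCGACATACTGCGTTTTCTATTT
CGCGATATCTTGGGAGGATCTGCCAATGTTGCGATTAAACGTAATTTCATATACTGCGTAACACATTTTG
AAGATAATGATTCAAATTCTCGGCACAAGGCCCTACGAAGTAAACGTGATCAGAGATTGCGGCGGGCGTT
CAAGGGTCCCTCTGGGAAGACACTATAAGAGCGTTAGAAAGGAGCTCAATCAACTGCTTGCGGAGGTTGC
GGGACGCCTGAATAACTCACCGTGTCTTCCTAAGATCATCAAAAATCCTAAGGTACTCCCCTCCAACATT
AAACGGACAACGCTATTTTGTCATGGCTCTTCCTGGGAGATGCTTTTGTGTATTACTCACATACGATAGC
TGACGTGGTCACGAACGGCTTAGTTTTCAGGAGATCAAAGCGTGTTGTAATGGAACACGAGTTGGCGGGT
CAAGGGCAACCGCTCGAGGGTAGTACTATATACGAAGCCAGCTCAGCGGTTAACGCATCTAATGAAACGT
AACCGGCCCATAGGTTTGTCTCACCGGT
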