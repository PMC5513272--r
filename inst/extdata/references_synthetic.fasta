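>MHC1ex3_synthetic
AGATATGAGAGTACTGGGCCCCTATTTGAAGTTCGGAATTACCCGACCCAGTCCAGAACAAGGTCGAGCGATAGCATTGA
GATCTTCGAGTGGCTACATGAAATATCACGTGGGACAAATAGGTCGCTACGCGAATTGGCGCGAGTTCACACGACGCCTA
CCGGCAAGAACGTTGCCACCGTACGGACAATCTGGCGGAGCGTACCGTACAAGTTATCATATGGTTTAAAAATACACGCC
AGCCATTATGAGGTCGAGAAA
>MHC2ex2_synthetic
ATGCGTCTGGAAGGCTGTTCCACGGCGAACTGCCCCAGTACTAAAGCCTTAAGTACCATGATGGGCATCCGGGGTAGCCC
ATATCTGCGCGGATGCCCAAGCACGCACACCCAGCTGCTGAGCGATCCGCATTCTGCGTCTGTTATCAAAGGGGGTTTCG
GGGAAACTGTGCAGTGTAGCTCTGTTCGAACCGCCGGACCCTCCGCAATATCAGTTATCAGAATCGAGTCTGGTTACCTA
TTTGAGGTTTTCGGGATACTAGTAGCAAAA
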