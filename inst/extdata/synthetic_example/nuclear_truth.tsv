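record_id	true_seq
pop1_ind1_c01	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c02	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGCCGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c03	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c04	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c05	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c06	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c07	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c08	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c09	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGCCGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind1_c10	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGCCGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind2_c01	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
pop1_ind2_c02	GGCGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCTCAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind2_c03	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind2_c04	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
pop1_ind2_c05	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
pop1_ind2_c06	CGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCTGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind2_c07	CGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCTGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop1_ind2_c08	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
pop1_ind2_c09	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
pop1_ind2_c10	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
pop2_ind1_c01	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGATCCG
pop2_ind1_c02	GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind1_c03	GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind1_c04	AGTGCCCACGAGAGTCTTAAGTGCTTTGCTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
pop2_ind1_c05	AGTGCCCACGAGAGTCTTAAGTGCTTTGCTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
pop2_ind1_c06	GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind1_c07	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGATCCG
pop2_ind1_c08	AGTGCCCACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
pop2_ind1_c09	AGTGCCCACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
pop2_ind1_c10	GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c01	GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c02	GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c03	GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c04	GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c05	GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c06	GGTGCCAACGAGAGTCTTAATTGCTTTACCGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c07	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGGAACCACCGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c08	GGTGCCAACGAGAGTCTTAATTGCTTTACCGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c09	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGGAACCACCGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
pop2_ind2_c10	GGTGCCAACGAGAGTCTTAATTGCTTTACTGGGAACCACCGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
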