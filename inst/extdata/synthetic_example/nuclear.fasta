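>pop1_ind1_c01
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c02
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGCCGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c03
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c04
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c05
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c06
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c07
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c08
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c09
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGCCGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind1_c10
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGCCGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind2_c01
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
>pop1_ind2_c02
GGCGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCTCAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind2_c03
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind2_c04
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
>pop1_ind2_c05
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
>pop1_ind2_c06
CGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCTGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind2_c07
CGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCTGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop1_ind2_c08
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
>pop1_ind2_c09
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
>pop1_ind2_c10
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGCACCTATGGGAACCG
>pop2_ind1_c01
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGATCCG
>pop2_ind1_c02
GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind1_c03
GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind1_c04
AGTGCCCACGAGAGTCTTAAGTGCTTTGCTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
>pop2_ind1_c05
AGTGCCCACGAGAGTCTTAAGTGCTTTGCTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
>pop2_ind1_c06
GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind1_c07
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGATCCG
>pop2_ind1_c08
AGTGCCCACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
>pop2_ind1_c09
AGTGCCCACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTCGGAGAACCTATGGGAACCG
>pop2_ind1_c10
GGTGACAACGAGAGTCTTAATTGCTTTACTGGGAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c01
GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c02
GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c03
GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c04
GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c05
GGTGCCAACGAGAGTCTTAAGTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGTTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c06
GGTGCCAACGAGAGTCTTAATTGCTTTACCGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c07
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGGAACCACCGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c08
GGTGCCAACGAGAGTCTTAATTGCTTTACCGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGG
GTGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c09
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGGAACCACCGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
>pop2_ind2_c10
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGGAACCACCGTCCTTTAGCGGACTCGTCACAACGTCCGG
GAGCTAGCGTCGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCG
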