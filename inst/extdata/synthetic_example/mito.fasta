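>pop1_ind1_c01
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c02
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTCCAGATAT
CAAAGCCGACGGCAGGGCTA
>pop1_ind1_c03
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c04
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c05
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c06
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c07
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c08
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c09
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind1_c10
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c01
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c02
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c03
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c04
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c05
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c06
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c07
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c08
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c09
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop1_ind2_c10
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c01
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCTCATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c02
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c03
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c04
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c05
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c06
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c07
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c08
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c09
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind1_c10
TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c01
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c02
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c03
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c04
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c05
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGAAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c06
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c07
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c08
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c09
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
>pop2_ind2_c10
TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATAT
CAAGGCCGACGGCAGGGATA
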