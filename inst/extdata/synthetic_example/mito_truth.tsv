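record_id	true_seq
pop1_ind1_c01	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c02	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTCCAGATATCAAAGCCGACGGCAGGGCTA
pop1_ind1_c03	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c04	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c05	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c06	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c07	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c08	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c09	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind1_c10	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c01	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c02	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c03	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c04	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c05	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c06	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c07	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c08	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c09	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop1_ind2_c10	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c01	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCTCATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c02	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c03	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c04	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c05	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c06	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c07	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c08	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c09	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind1_c10	TTAGTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTACAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c01	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c02	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c03	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c04	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c05	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGAAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c06	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c07	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c08	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c09	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
pop2_ind2_c10	TTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATA
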