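individual_id	population	strategy	ploidy	marker	code_table	frame_offset	coding_ranges
pop1_ind1	pop1	fissiparous	3	TMED9	1	0	1-60
pop1_ind2	pop1	fissiparous	3	TMED9	1	0	1-60
pop2_ind1	pop2	fissiparous	3	TMED9	1	0	1-60
pop2_ind2	pop2	fissiparous	3	TMED9	1	0	1-60
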