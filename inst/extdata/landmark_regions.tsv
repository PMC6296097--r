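name	part	start	end
terminal_view_7A	chr7A_part2	268221621	286659250
terminal_introgression_7A	chr7A_part2	272100000	286659250
vrn_b1_gene	chr5B_part2	122425505	122445491
cnv_gain_6D	chr6D_part1	430251567	448876599
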