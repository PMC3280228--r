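# dialect: rank
# Within-grape duplicated genome regions (fixture encoding of the six
# published block pairs; intervals are rank windows on layout_vitis.tsv).
block_id	genome_a	chr_a	start_a	end_a	genome_b	chr_b	start_b	end_b	orientation
b1	vitis	chr4	1	2	vitis	chr11	1	2	same
b2	vitis	chr4	1	2	vitis	chr8	3	5	same
b3	vitis	chr4	9	10	vitis	chr8	6	8	inverted
b4	vitis	chr6	1	2	vitis	chr6	6	7	same
b5	vitis	chr4	3	5	vitis	chr11	3	5	same
b6	vitis	chr6	3	5	vitis	chr11	6	8	same
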