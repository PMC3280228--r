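# dialect: rank
# Grape-Arabidopsis synteny blocks (fixture encoding of the published
# ortholog correspondences; side A ranks refer to layout_vitis.tsv, side B
# ranks to layout_arabidopsis_synthetic.tsv).
block_id	genome_a	chr_a	start_a	end_a	genome_b	chr_b	start_b	end_b	orientation
x1	vitis	chr4	9	10	arabidopsis	ath1	1	3	same
x2	vitis	chr6	6	7	arabidopsis	ath2	1	3	same
x3	vitis	chr8	1	2	arabidopsis	ath3	1	3	same
x4	vitis	chr8	9	10	arabidopsis	ath4	1	3	inverted
x5	vitis	chr18	4	5	arabidopsis	ath4	4	6	same
x6	vitis	chr11	9	11	arabidopsis	ath5	1	3	same
x7	vitis	chr4	1	2	arabidopsis	ath1	4	6	same
x8	vitis	chr4	1	2	arabidopsis	ath3	4	6	same
x9	vitis	chr11	1	2	arabidopsis	ath3	4	6	same
x10	vitis	chr6	3	5	arabidopsis	ath2	4	6	same
x11	vitis	chr11	6	8	arabidopsis	ath3	7	9	same
x12	vitis	chr6	3	5	arabidopsis	ath3	7	9	same
x13	vitis	chr2	1	3	arabidopsis	ath5	4	6	same
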