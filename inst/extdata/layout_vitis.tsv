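# Grape gene-locus catalog derived from the packaged gene table.
# Fixture convention: loci are ordered by numeric locus ID as a proxy for
# chromosomal order; chromosome assignments and background (non-ALDH) loci
# are fixture scaffolding chosen to encode the published adjacency facts
# (the family-5 triple is strictly adjacent; the family-6 pair has exactly
# one intervening locus; no other same-family neighbours are within one
# intervening locus).
genome	chromosome	rank	locus_id	gene_id
vitis	chr2	1	GSVIVG01000335001	NA
vitis	chr2	2	GSVIVG01000336001	VvALDH6B3
vitis	chr2	3	GSVIVG01000337001	NA
vitis	chr2	4	GSVIVG01000338001	VvALDH6B5
vitis	chr2	5	GSVIVG01000339001	NA
vitis	chrUn	1	GSVIVG01003951001	VvALDH6B7
vitis	chr4	1	GSVIVG01007784001	VvALDH2B4
vitis	chr4	2	GSVIVG01007800001	NA
vitis	chr4	3	GSVIVG01007810001	NA
vitis	chr4	4	GSVIVG01007829001	VvALDH10A9
vitis	chr4	5	GSVIVG01007900001	NA
vitis	chr4	6	GSVIVG01008000001	NA
vitis	chr4	7	GSVIVG01008047001	VvALDH12A1
vitis	chr4	8	GSVIVG01008500001	NA
vitis	chr4	9	GSVIVG01008700001	NA
vitis	chr4	10	GSVIVG01008845001	VvALDH3H1
vitis	chr6	1	GSVIVG01015062001	VvALDH7B5
vitis	chr6	2	GSVIVG01015500001	NA
vitis	chr6	3	GSVIVG01016000001	NA
vitis	chr6	4	GSVIVG01016467001	VvALDH18B1
vitis	chr6	5	GSVIVG01016600001	NA
vitis	chr6	6	GSVIVG01016700001	NA
vitis	chr6	7	GSVIVG01016734001	VvALDH7D1
vitis	chr8	1	GSVIVG01018842001	VvALDH3F1
vitis	chr8	2	GSVIVG01019000001	NA
vitis	chr8	3	GSVIVG01019500001	NA
vitis	chr8	4	GSVIVG01020224001	VvALDH2B8
vitis	chr8	5	GSVIVG01021000001	NA
vitis	chr8	6	GSVIVG01021500001	NA
vitis	chr8	7	GSVIVG01022356001	VvALDH3H5
vitis	chr8	8	GSVIVG01022800001	NA
vitis	chr8	9	GSVIVG01023000001	NA
vitis	chr8	10	GSVIVG01023590001	VvALDH11B1
vitis	chr8	11	GSVIVG01024000001	NA
vitis	chr8	12	GSVIVG01024500001	NA
vitis	chr8	13	GSVIVG01025276001	VvALDH3J1
vitis	chr11	1	GSVIVG01032500001	VvALDH2B9
vitis	chr11	2	GSVIVG01032550001	NA
vitis	chr11	3	GSVIVG01032560001	NA
vitis	chr11	4	GSVIVG01032588001	VvALDH10B1
vitis	chr11	5	GSVIVG01033000001	NA
vitis	chr11	6	GSVIVG01033500001	NA
vitis	chr11	7	GSVIVG01034097001	VvALDH18B3
vitis	chr11	8	GSVIVG01034500001	NA
vitis	chr11	9	GSVIVG01034800001	NA
vitis	chr11	10	GSVIVG01035003001	VvALDH22A1
vitis	chr11	11	GSVIVG01035400001	NA
vitis	chr11	12	GSVIVG01035600001	NA
vitis	chr11	13	GSVIVG01035891001	VvALDH11A3
vitis	chr18	1	GSVIVG01036700001	NA
vitis	chr18	2	GSVIVG01036719001	VvALDH5F1
vitis	chr18	3	GSVIVG01036720001	VvALDH5F2
vitis	chr18	4	GSVIVG01036721001	VvALDH5F3
vitis	chr18	5	GSVIVG01036800001	NA
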