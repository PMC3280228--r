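# Synthetic Arabidopsis gene-locus catalog (fixture scaffolding): gene
# content and family membership follow the published ortholog lists, but
# chromosome assignments, ranks and background loci are invented, since the
# source prints no Arabidopsis coordinates.
genome	chromosome	rank	locus_id	gene_id
arabidopsis	ath1	1	AT1G00100	NA
arabidopsis	ath1	2	AT1G00200	AthALDH3H1
arabidopsis	ath1	3	AT1G00300	NA
arabidopsis	ath1	4	AT1G00400	NA
arabidopsis	ath1	5	AT1G00500	AthALDH2B4
arabidopsis	ath1	6	AT1G00600	NA
arabidopsis	ath2	1	AT2G00100	NA
arabidopsis	ath2	2	AT2G00200	AthALDH7B4
arabidopsis	ath2	3	AT2G00300	NA
arabidopsis	ath2	4	AT2G00400	NA
arabidopsis	ath2	5	AT2G00500	AthALDH18A1
arabidopsis	ath2	6	AT2G00600	NA
arabidopsis	ath3	1	AT3G00100	NA
arabidopsis	ath3	2	AT3G00200	AthALDH3F1
arabidopsis	ath3	3	AT3G00300	NA
arabidopsis	ath3	4	AT3G00400	NA
arabidopsis	ath3	5	AT3G00500	AthALDH2B7
arabidopsis	ath3	6	AT3G00600	NA
arabidopsis	ath3	7	AT3G00700	NA
arabidopsis	ath3	8	AT3G00800	AthALDH18A2
arabidopsis	ath3	9	AT3G00900	NA
arabidopsis	ath4	1	AT4G00100	NA
arabidopsis	ath4	2	AT4G00200	AthALDH11A3
arabidopsis	ath4	3	AT4G00300	NA
arabidopsis	ath4	4	AT4G00400	NA
arabidopsis	ath4	5	AT4G00500	AthALDH5F1
arabidopsis	ath4	6	AT4G00600	NA
arabidopsis	ath5	1	AT5G00100	NA
arabidopsis	ath5	2	AT5G00200	AthALDH22A1
arabidopsis	ath5	3	AT5G00300	NA
arabidopsis	ath5	4	AT5G00400	NA
arabidopsis	ath5	5	AT5G00500	NA
arabidopsis	ath5	6	AT5G00600	NA
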