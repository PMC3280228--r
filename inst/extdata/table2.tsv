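organism	group	f1	f2	f3	f4	f5	f6	f7	f8	f9	f10	f11	f12	f13	f14	f15	f16	f17	f18	f19	f20	f21	f22	f23	f24
V. vinifera	vascular plant	-	3	4	-	3	3	2	-	-	2	2	1	-	-	-	-	-	2	-	-	-	1	-	-
A. thaliana	vascular plant	-	3	3	-	1	1	1	-	-	2	1	1	-	-	-	-	-	2	-	-	-	1	-	-
Z. mays	vascular plant	-	6	5	-	2	1	1	-	-	3	1	1	-	-	-	-	-	3	-	-	-	1	-	-
O. sativa	vascular plant	-	5	5	-	1	1	1	-	-	2	1	2	-	-	-	-	-	2	-	-	-	1	-	-
P. patens	moss	-	2	5	-	2	1	1	-	-	1	5	1	-	-	-	-	-	-	-	-	1	-	1	-
C. reinhardtii	alga	-	1	-	-	2	1	-	-	-	1	1	1	-	-	-	-	-	-	-	-	-	-	-	1
O. tauri	alga	-	-	1	-	1	-	-	-	-	1	1	1	-	-	-	-	-	-	-	-	-	1	-	-
H. sapiens	mammal	6	1	4	1	1	1	1	1	1	-	-	-	-	-	-	1	-	1	-	-	-	-	-	-
M. musculus	mammal	7	1	4	1	1	1	1	1	1	-	-	-	-	-	-	1	-	1	-	-	-	-	-	-
R. norvegicus	mammal	7	1	4	-	1	1	1	1	1	-	-	-	-	-	-	1	-	1	-	-	-	-	-	-
Fungi	fungus	+	-	-	+	+	-	-	-	-	+	-	-	-	+	+	+	-	+	-	-	-	-	-	-
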