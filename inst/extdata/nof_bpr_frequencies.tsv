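chrom	start	end	breast	colorectal	gastric	lung	medulloblastoma	ovarian	prostate	renal	normal	class
2	172338300	172339964	7.96	14.29	0.29	1.72	2.26	8.21	0.00	7.34	0.69	3
2	172345151	172348021	4.51	14.29	0.00	1.37	1.63	7.73	0.00	7.34	0.69	3
4	3027493	3027897	0.00	0.00	11.47	0.00	0.00	0.00	0.00	1.83	1.39	3
4	3029623	3035631	0.00	0.00	11.76	0.00	0.00	0.00	0.00	1.83	1.16	3
4	9994215	9996852	12.47	0.00	1.47	1.37	0.00	0.00	0.00	3.67	0.00	2
4	9997801	10001833	13.79	0.00	7.35	3.44	0.00	0.00	0.00	3.67	0.00	2
5	4430296	4431868	0.27	0.00	11.18	0.69	0.00	0.00	0.00	0.00	1.16	1
5	4443854	4445976	0.27	0.00	18.53	2.06	0.00	0.00	0.00	0.00	0.93	3
5	61569169	61572989	0.00	0.00	0.00	0.34	1.09	0.00	0.00	12.84	0.46	2
5	126152745	126158200	0.27	0.00	0.00	1.37	1.54	0.00	0.00	10.09	1.16	3
6	67048629	67049406	2.39	12.70	2.65	2.75	1.18	0.48	0.00	4.59	0.46	2
6	77422497	77439868	7.16	10.05	2.35	5.15	6.07	4.83	1.67	5.50	3.24	3
7	35396655	35397567	0.00	0.00	1.03	3.82	0.27	11.59	5.83	0.00	8.33	3
8	6104977	6107427	1.59	15.87	1.18	1.03	1.36	5.31	0.00	8.26	0.23	2
8	39225941	39288762	7.69	12.17	4.71	8.25	8.79	4.35	0.83	9.17	5.56	3
8	39397732	39398022	7.43	11.11	4.71	8.25	8.79	4.83	0.83	9.17	5.09	3
8	43778914	46924211	9.02	3.70	2.65	7.22	0.63	8.21	14.17	5.50	3.01	3
9	9337599	9338146	0.27	0.53	13.53	0.34	0.00	0.00	0.00	0.00	0.46	1
9	9338417	9339871	0.27	0.53	11.76	0.69	0.00	0.00	0.00	0.00	0.46	1
10	44051819	44065519	0.53	0.00	0.00	1.03	0.36	0.00	0.00	10.09	0.23	2
11	9241448	9250359	1.06	1.06	0.29	1.72	2.90	0.97	0.00	11.01	0.93	3
14	35070371	35076347	0.00	0.00	0.00	0.34	0.45	0.00	0.00	10.09	0.46	1
16	70842097	70854381	15.38	0.00	0.29	1.03	1.81	0.48	0.00	0.00	0.23	2
16	85082710	85091864	0.27	4.76	0.29	0.34	15.58	1.45	0.00	10.09	0.23	2
16	85091864	85092483	11.14	22.75	9.41	26.12	27.90	21.26	0.00	11.01	4.86	3
16	85092748	85092892	9.81	27.51	9.71	25.43	43.48	22.71	0.00	21.10	5.09	3
17	18917513	18917915	1.86	1.59	0.29	0.69	10.05	0.00	0.00	0.00	0.00	2
17	18917915	19168912	0.53	0.53	0.00	0.00	15.40	0.00	0.00	0.00	0.00	1
18	4976160	4979612	0.27	16.40	4.12	0.00	1.36	0.00	0.00	25.69	11.81	3
18	4989683	4990804	0.27	11.64	2.35	0.00	2.08	0.00	2.50	20.18	11.34	3
21	23655764	23655900	0.00	0.53	10.00	12.03	0.63	5.31	3.33	0.00	6.71	3
21	23664658	23667121	0.53	2.65	11.47	13.40	3.62	11.59	7.50	0.92	9.03	3
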