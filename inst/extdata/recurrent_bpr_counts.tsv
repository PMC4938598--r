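chrom	start	end	breast	colorectal	gastric	lung	medulloblastoma	ovarian	prostate	renal	cancer	normal
1	148916177	149040066	11	5	9	9	23	4	1	0	62	5
2	172338300	172339964	30	27	1	5	25	17	0	8	113	3
2	172345151	172348021	17	27	0	4	18	16	0	8	90	3
2	242718444	242725752	7	8	3	2	51	1	1	7	80	6
4	9994215	9996852	47	0	5	4	0	0	0	4	60	0
4	9997801	10001833	52	0	25	10	0	0	0	4	91	0
4	70950894	70951184	8	12	0	0	96	0	0	5	121	0
4	70951806	70953579	8	12	0	0	96	0	0	5	121	0
5	4443854	4445976	1	0	63	6	0	0	0	0	70	4
6	29850274	29871636	8	3	20	10	31	14	4	2	92	15
6	29899493	29899677	2	1	11	3	29	8	3	0	57	9
6	67048629	67049406	9	24	9	8	13	1	0	5	69	2
6	77422497	77439868	27	19	8	15	67	10	2	6	154	14
6	77452270	77452804	15	15	7	11	26	5	0	1	80	6
6	77452804	77461073	12	4	1	4	41	5	1	5	73	8
6	78962626	78979398	20	15	12	7	108	8	1	5	176	12
6	79026686	79039234	15	15	7	5	104	8	0	4	158	11
8	5594132	5601352	8	6	7	4	29	5	2	2	63	6
8	6104977	6107427	6	30	4	3	15	11	0	9	78	1
8	39225941	39288762	29	23	16	24	97	9	1	10	209	24
8	39397732	39398022	28	21	16	24	97	10	1	10	207	22
8	43778914	46924211	34	7	9	21	7	17	17	6	118	13
8	137677896	137681619	8	5	2	6	29	3	2	4	59	10
11	9241448	9250359	4	2	1	5	32	2	0	12	58	4
11	86410303	86410905	7	13	1	1	56	4	0	3	85	1
11	86412698	86412880	7	13	10	3	59	3	0	3	98	1
12	33299791	33302438	11	7	4	10	32	5	1	2	72	10
12	33303866	33312197	24	7	3	10	43	5	1	3	96	11
14	41606882	41606899	2	7	4	2	50	0	0	3	68	5
14	41653977	41670102	2	7	4	2	50	0	0	3	68	6
16	70842097	70854381	58	0	1	3	20	1	0	0	83	1
16	71202489	71207879	30	0	2	3	19	8	0	0	62	0
16	85082710	85091864	1	9	1	1	172	3	0	11	198	1
16	85091864	85092483	42	43	32	76	308	44	0	12	557	21
16	85092748	85092892	37	52	33	74	480	47	0	23	746	22
17	18917513	18917915	7	3	1	2	111	0	0	0	124	0
17	18917915	19168912	2	1	0	0	170	0	0	0	173	0
17	44162597	44165803	12	7	4	3	50	2	3	8	89	5
17	44572303	44789285	17	12	4	6	61	4	4	7	115	5
17	54158456	54163047	10	0	5	0	40	1	1	2	59	6
17	54172591	54173463	11	0	10	3	33	5	1	1	64	3
18	4976160	4979612	1	31	14	0	15	0	0	28	89	51
18	4989683	4990804	1	22	8	0	23	0	3	22	79	49
21	20346687	20347871	4	12	0	0	43	0	0	7	66	0
21	20353826	20353905	4	13	2	0	43	0	0	6	68	0
21	23655764	23655900	0	1	34	35	7	11	4	0	92	29
21	23664658	23667121	2	5	39	39	40	24	9	1	159	39
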