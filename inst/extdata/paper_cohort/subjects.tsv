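subject_id	sex	age_years	tics	ocd	absent_speech	seizures	regression	id_severity	affected_first_degree_relative	mother_affected_significant_ndd	father_affected_significant_ndd	mito_domains	lab_report_positive
1	M	20	0	0	1	0	none	severe	0	0	0	neurodevelopmental	1
2	F	10	1	1	0	1	multiple	moderate	0	0	0	neurodevelopmental	1
3	F	14	0	1	0	0	multiple	moderate	0	0	0	neurodevelopmental	0
4	M	5	0	0	0	0	none	moderate	0	0	0	neurodevelopmental	0
5	M	22	0	0	0	0	none	none	0	0	0	neurodevelopmental	0
6	M	10	0	0	1	0	single	severe	1	1	0	neurodevelopmental	0
7	M	13	0	0	0	0	none	none	1	0	0	neurodevelopmental	1
8	F	6	0	0	0	0	single	mild	0	0	0	neurodevelopmental	0
9	M	22	0	0	1	1	none	severe	0	0	0	neurodevelopmental	1
10	M	5	0	0	1	0	none	none	1	0	0	neurodevelopmental	0
11	M	12	0	0	0	0	single	mild	1	0	0	neurodevelopmental,functional,immunological	0
12	F	4	0	0	1	1	none	severe	0	0	0	neurodevelopmental	0
13	M	26	0	0	0	0	none	severe	1	0	0	neurodevelopmental	1
14	M	14	1	1	0	0	single	none	0	0	0	neurodevelopmental	0
15	M	19	1	0	0	1	single	mild	0	0	0	neurodevelopmental	1
16	M	6	0	0	0	0	single	none	0	0	0	neurodevelopmental	0
17	M	10	0	0	1	0	none	severe	0	0	0	neurodevelopmental	0
18	F	12	1	0	0	0	none	none	1	0	1	neurodevelopmental	0
19	M	14	1	0	1	0	multiple	moderate	0	0	0	neurodevelopmental	0
20	M	14	1	0	1	1	single	none	0	0	0	neurodevelopmental	0
21	M	16	0	1	0	1	single	moderate	1	0	0	neurodevelopmental	0
22	M	6	0	0	1	0	multiple	severe	1	1	0	neurodevelopmental	1
23	M	5	0	1	1	0	single	moderate	0	0	0	neurodevelopmental	0
24	F	25	0	1	0	1	none	mild	0	0	0	neurodevelopmental	0
25	F	16	0	1	0	0	none	mild	0	0	0	neurodevelopmental	0
26	M	5	0	0	0	0	single	moderate	0	0	0	neurodevelopmental	0
27	M	16	0	1	0	0	single	moderate	0	0	0	neurodevelopmental	0
28	M	22	0	1	0	1	none	none	0	0	0	neurodevelopmental	1
29	M	10	1	0	0	0	single	moderate	0	0	0	neurodevelopmental	0
30	M	13	0	0	0	0	none	severe	1	0	0	neurodevelopmental	0
31	M	3	0	1	0	0	single	mild	0	0	0	neurodevelopmental	0
32	M	12	0	0	0	0	none	mild	1	0	1	neurodevelopmental	1
33	M	7	0	0	0	0	none	moderate	0	0	0	neurodevelopmental	1
34	M	19	1	1	0	0	single	severe	1	0	1	neurodevelopmental	0
35	M	22	0	0	0	1	none	moderate	0	0	0	neurodevelopmental	1
36	F	8	0	1	0	0	none	none	1	1	0	neurodevelopmental	1
37	M	5	0	0	1	0	single	mild	0	0	0	neurodevelopmental	0
38	M	17	1	0	0	0	single	mild	0	0	0	neurodevelopmental	0
39	M	12	1	0	0	1	none	mild	1	0	1	neurodevelopmental	0
40	M	9	1	1	0	0	none	none	0	0	0	neurodevelopmental	0
41	M	10	0	0	0	1	single	moderate	0	0	0	neurodevelopmental	0
42	M	13	0	0	0	0	multiple	mild	0	0	0	neurodevelopmental	1
43	F	18	0	1	0	1	none	moderate	0	0	0	neurodevelopmental	0
44	M	6	0	0	0	0	multiple	severe	1	1	0	neurodevelopmental	0
45	M	15	0	0	0	1	none	mild	0	0	0	neurodevelopmental	0
46	F	16	0	1	1	1	multiple	severe	0	0	0	neurodevelopmental	0
47	M	7	1	0	1	0	multiple	severe	0	0	0	neurodevelopmental	0
48	F	13	0	0	0	1	none	none	1	0	0	neurodevelopmental,neuropsychiatric,functional,metabolic	1
49	M	7	1	1	0	0	single	severe	1	0	0	neurodevelopmental	0
50	F	7	0	0	0	0	single	none	0	0	0	neurodevelopmental	0
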