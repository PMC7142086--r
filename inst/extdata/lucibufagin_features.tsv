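feature	cluster	feature_id	adduct	formula
1	75	Ppyr_hemolymph_extract_436.269439697265_13.538295	M+H	C24H37NO6
2	75	Ppyr_hemolymph_extract_453.296081542968_13.538295	M+NH4	C24H37NO6
3	76	Ppyr_hemolymph_extract_434.25390625_13.471111	M+H	C24H35NO6
4	76	Ppyr_hemolymph_extract_452.264434814453_8.0686129	M+H	C24H37NO7
5	76	Ppyr_hemolymph_extract_469.291137695312_8.0686129	M+NH4	C24H37NO7
6	77	Ppyr_hemolymph_extract_507.222839355468_13.718764	M+H	C26H34O10
7	77	Ppyr_hemolymph_extract_524.249481201171_13.718764	M+NH4	C26H34O10
8	77	Ppyr_hemolymph_extract_549.233520507812_15.795523	M+H	C28H36O11
9	78	Ppyr_hemolymph_extract_1114.52197265625_19.262445	NA	NA
10	79	Ppyr_hemolymph_extract_531.222991943359_16.840886	M+H	C28H34O10
11	80	Ppyr_hemolymph_extract_1082.49517822265_19.965233	2M+NH4	C28H36O10
12	80	Ppyr_hemolymph_extract_1100.50646972656_18.35508	NA	NA
13	80	Ppyr_hemolymph_extract_1082.49487304687_21.307386	2M+NH4	C28H36O10
14	80	Ppyr_hemolymph_extract_1082.49530029296_18.991166	2M+NH4	C28H36O10
15	81	Ppyr_hemolymph_extract_517.243591308593_15.954252	M+H	C28H36O9
16	81	Ppyr_hemolymph_extract_535.254180908203_12.579138	M+H	C28H38O10
17	82	Ppyr_hemolymph_extract_1082.49475097656_15.123002	2M+NH4	C28H36O10
18	82	Ppyr_hemolymph_extract_1110.52667236328_17.431269	2M+NH4	C29H38O10
19	82	Ppyr_hemolymph_extract_491.227569580078_12.962671	M+H	C26H34O9
20	82	Ppyr_hemolymph_extract_491.227661132812_10.204906	M+H	C26H34O9
21	82	Ppyr_hemolymph_extract_533.237884521484_15.123002	M+H	C28H36O10
22	82	Ppyr_hemolymph_extract_547.254028320312_17.431269	M+H	C29H38O10
23	82	Ppyr_hemolymph_extract_550.264221191406_15.123002	M+NH4	C28H36O10
24	82	Ppyr_hemolymph_extract_561.269470214843_19.784291	M+H	C30H40O10
25	82	Ppyr_hemolymph_extract_561.26953125_19.535629	M+H	C30H40O10
26	82	Ppyr_hemolymph_extract_564.280517578125_17.431269	M+NH4	C29H38O10
27	82	Ppyr_hemolymph_extract_574.264343261718_15.123002	M+ACN+H	C28H36O10
28	82	Ppyr_hemolymph_extract_578.296081542968_19.784291	M+NH4	C30H40O10
29	83	Ppyr_hemolymph_extract_1065.4677734375_15.366083	2M+H	C28H36O10
30	83	Ppyr_hemolymph_extract_1082.49499511718_15.366083	2M+NH4	C28H36O10
31	83	Ppyr_hemolymph_extract_491.227600097656_13.224755	M+H	C26H34O9
32	83	Ppyr_hemolymph_extract_491.228057861328_11.943648	M+H	C26H34O9
33	83	Ppyr_hemolymph_extract_533.238098144531_15.366083	M+H	C28H36O10
34	83	Ppyr_hemolymph_extract_547.253814697265_17.719947	M+H	C29H38O10
35	83	Ppyr_hemolymph_extract_547.254211425781_17.046113	M+H	C29H38O10
36	83	Ppyr_hemolymph_extract_550.264404296875_15.366083	M+NH4	C28H36O10
37	83	Ppyr_hemolymph_extract_561.269348144531_18.878158	M+H	C30H40O10
38	83	Ppyr_hemolymph_extract_561.269592285156_20.078779	M+H	C30H40O10
39	83	Ppyr_hemolymph_extract_564.280212402343_17.719947	M+NH4	C29H38O10
40	83	Ppyr_hemolymph_extract_578.295959472656_18.878158	M+NH4	C30H40O10
41	108	Ppyr_hemolymph_extract_449.217010498046_9.3229572	M+H	C24H32O8
42	108	Ppyr_hemolymph_extract_491.227844238281_14.49087	M+H	C26H34O9
43	109	Ppyr_hemolymph_extract_1615.72888183593_15.123002	3M+NH4	C28H36O10
44	110	Ppyr_hemolymph_extract_449.217071533203_10.789573	M+H	C24H32O8
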