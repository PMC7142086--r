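mz_average	mz_min	mz_max	pct_cluster_82	pct_cluster_83	formula	ppm_reported	incidence_count	incidence_pct
135.0443	135.0434	135.0448	100	0	C8H7O2	1.8	16	36
205.0863	205.0840	205.0872	100	0	C12H13O3	1.8	18	41
413.1965	413.1950	413.1970	100	0	C24H29O6	1.5	15	34
105.0701	105.0698	105.0707	100	100	C8H9	2.1	36	82
121.0648	121.0644	121.0653	100	100	C8H9O	0.1	41	93
147.0805	147.0756	147.0812	100	100	C10H11O	1.1	35	80
185.0961	185.0924	185.0975	100	100	C13H13O	-1.0	27	61
151.0392	151.0388	151.0396	0	100	C8H7O3	1.5	14	32
265.1592	265.1540	265.1670	0	100	C19H21O	1.9	17	39
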