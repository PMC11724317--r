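duplex_id	reference_id	ddg37_exp	dg_pred	ddg_pred	orientation_pred	hbonds	orientation_nmr
A-U	A-U	0.00	1.86	0.00	anti-anti	1.98	anti-anti
7A-U	A-U	4.15	5.43	3.57	anti-anti	1.16	NA
7AL-U	A-U	2.20	2.85	0.99	syn-anti	1.00	NA
A-C	A-C	0.00	4.34	0.00	anti-syn	1.00	NA
7A-C	A-C	2.07	5.51	1.17	syn-anti	0.97	NA
7AL-C	A-C	0.39	4.76	0.42	anti-anti	0.99	NA
A-A	A-A	0.00	3.48	0.00	anti-anti	0.96	anti-anti
7A-A	A-A	-0.73	1.50	-1.98	anti-anti	1.99	anti-anti
7AL-A	A-A	-1.80	1.44	-2.04	anti-anti	1.99	anti-anti
A-G	A-G	0.00	2.81	0.00	syn-anti	1.99	NA
7A-G	A-G	0.99	2.10	-0.71	syn-anti	1.54	syn-anti
7AL-G	A-G	-1.28	1.22	-1.59	syn-anti	1.75	syn-anti
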