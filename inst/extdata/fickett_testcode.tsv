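# Fickett (1982) Nucleic Acids Res 10:5303-5318. TESTCODE lookup tables.
# kind: position = codon-position asymmetry parameter (max/(min+1) of the three
#   codon-position counts); content = base fraction of the sequence.
# threshold: a parameter value v maps to the first row (scanning top-down within
#   its base and kind) with v >= threshold; the final threshold is 0 so every
#   non-negative value maps to a row.
kind	base	threshold	probability	weight
position	A	1.9	0.51	0.26
position	A	1.8	0.55	0.26
position	A	1.7	0.57	0.26
position	A	1.6	0.52	0.26
position	A	1.5	0.48	0.26
position	A	1.4	0.58	0.26
position	A	1.3	0.57	0.26
position	A	1.2	0.54	0.26
position	A	1.1	0.50	0.26
position	A	0.0	0.36	0.26
position	C	1.9	0.29	0.18
position	C	1.8	0.44	0.18
position	C	1.7	0.55	0.18
position	C	1.6	0.49	0.18
position	C	1.5	0.52	0.18
position	C	1.4	0.60	0.18
position	C	1.3	0.60	0.18
position	C	1.2	0.56	0.18
position	C	1.1	0.51	0.18
position	C	0.0	0.38	0.18
position	G	1.9	0.62	0.31
position	G	1.8	0.67	0.31
position	G	1.7	0.74	0.31
position	G	1.6	0.65	0.31
position	G	1.5	0.61	0.31
position	G	1.4	0.62	0.31
position	G	1.3	0.66	0.31
position	G	1.2	0.60	0.31
position	G	1.1	0.46	0.31
position	G	0.0	0.35	0.31
position	T	1.9	0.51	0.33
position	T	1.8	0.60	0.33
position	T	1.7	0.69	0.33
position	T	1.6	0.64	0.33
position	T	1.5	0.62	0.33
position	T	1.4	0.67	0.33
position	T	1.3	0.58	0.33
position	T	1.2	0.48	0.33
position	T	1.1	0.39	0.33
position	T	0.0	0.28	0.33
content	A	0.33	0.40	0.11
content	A	0.31	0.55	0.11
content	A	0.29	0.58	0.11
content	A	0.27	0.58	0.11
content	A	0.25	0.52	0.11
content	A	0.23	0.48	0.11
content	A	0.21	0.45	0.11
content	A	0.19	0.45	0.11
content	A	0.17	0.38	0.11
content	A	0.00	0.19	0.11
content	C	0.33	0.50	0.12
content	C	0.31	0.63	0.12
content	C	0.29	0.59	0.12
content	C	0.27	0.50	0.12
content	C	0.25	0.41	0.12
content	C	0.23	0.30	0.12
content	C	0.21	0.24	0.12
content	C	0.19	0.23	0.12
content	C	0.17	0.30	0.12
content	C	0.00	0.17	0.12
content	G	0.33	0.21	0.15
content	G	0.31	0.40	0.15
content	G	0.29	0.47	0.15
content	G	0.27	0.46	0.15
content	G	0.25	0.45	0.15
content	G	0.23	0.50	0.15
content	G	0.21	0.56	0.15
content	G	0.19	0.67	0.15
content	G	0.17	0.72	0.15
content	G	0.00	0.31	0.15
content	T	0.33	0.30	0.14
content	T	0.31	0.49	0.14
content	T	0.29	0.56	0.14
content	T	0.27	0.53	0.14
content	T	0.25	0.48	0.14
content	T	0.23	0.48	0.14
content	T	0.21	0.52	0.14
content	T	0.19	0.60	0.14
content	T	0.17	0.46	0.14
content	T	0.00	0.17	0.14
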