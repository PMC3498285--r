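feature	effect	p	cluster	opposite_of
ybbK	3.07	0.01	C6	sigW
ybbJ	2.68	0.01	C6	sigW
S928	2.25	0.01	C5	.
S1380	1.16	0.01	C10	.
ykzV	1.13	0.01	C2	.
S1026	0.92	0.01	C2	.
cotT	0.91	0.01	C2	.
yodI	0.83	0.01	C2	.
S1030	0.82	0.01	C3	.
murG	0.77	0.01	C4	.
S981	0.73	0.01	C17	yqaR
ymaG	0.68	0.01	C2	.
S655	0.66	0.01	C17	fosB
S862	0.65	0.01	C2	.
S1356	0.64	0.01	C3	.
yrzI	0.63	0.01	C2	.
S613	0.62	0.01	C27	.
S663	0.61	0.01	C17	.
S1405	0.60	0.01	C2	.
S254	0.60	0.01	C17	.
ykzW	0.59	0.01	C30	.
S653	0.57	0.01	C17	.
ydeH	0.56	0.01	C17	.
yqaR	0.54	0.01	C6	.
S360	0.54	0.01	C35	.
S118	0.52	0.01	C52	yuaI
obg	0.50	0.01	C3	.
cotU	0.50	0.01	C2	.
yqxD	0.46	0.01	C153	.
S278	0.46	0.01	C17	.
pssA	0.46	0.01	C3	.
S303	0.45	0.01	C3	.
comK	0.44	0.01	C1	.
yktD	0.43	0.01	C115	.
S1543	0.43	0.01	C35	.
S95	0.42	0.01	C35	.
S831	0.42	0.01	C2	.
S427	0.42	0.01	C2	.
S924	0.41	0.01	C17	.
yfzA	0.41	0.01	C17	.
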