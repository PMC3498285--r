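feature	effect	p	q_lt_0.05	cluster	motif	operon	operon_pos	downstream_of	salt_induced	prior_regulon	conclusion_printed	call_expected
rsiW	-6.84	0.01	TRUE	C9	Yes	sigW-rsiW	2	.	TRUE	TRUE	core sigW	core
sigW	-6.83	0.01	TRUE	C9	Yes	sigW-rsiW	1	.	TRUE	TRUE	core sigW	core
spo0M	-4.92	0.01	TRUE	C9	Yes	spo0M	1	.	TRUE	TRUE	core sigW	core
S691	-3.66	0.01	TRUE	C9	Yes	S691-yoaG-S690	1	.	TRUE	FALSE	core sigW	core
yeaA	-3.61	0.01	TRUE	C2	Yes	yeaA-ydjP-ydjO	1	.	TRUE	TRUE	Secondary sigW	secondary
ysdB	-3.54	0.01	TRUE	C9	Yes	ysdB	1	.	TRUE	TRUE	core sigW	core
yjoB	-3.40	0.01	TRUE	C9	Yes	yjoB	1	.	TRUE	TRUE	core sigW	core
ydjP	-3.34	0.01	TRUE	C2	Yes	yeaA-ydjP-ydjO	2	.	TRUE	TRUE	Secondary sigW	secondary
S462	-3.23	0.01	TRUE	C9	Yes	S462	1	.	TRUE	FALSE	core sigW	core
yxjI	-3.12	0.01	TRUE	C9	Yes	S1495-yxjJ-yxjI	3	.	TRUE	TRUE	core sigW	core
yoaG	-3.07	0.01	TRUE	C9	Yes	S691-yoaG-S690	2	.	TRUE	TRUE	core sigW	core
fosB	-3.03	0.01	TRUE	C9	Yes	fosB-S658-S659	1	.	TRUE	TRUE	core sigW	core
ythP	-2.98	0.01	TRUE	C9	Yes	ythP-ythQ	1	.	TRUE	TRUE	core sigW	core
S690	-2.90	0.01	TRUE	C9	Yes	S691-yoaG-S690	3	.	TRUE	FALSE	core sigW	core
S1495	-2.89	0.01	TRUE	C9	Yes	S1495-yxjJ-yxjI	1	.	TRUE	FALSE	core sigW	core
ythQ	-2.74	0.01	TRUE	C9	Yes	ythP-ythQ	2	.	TRUE	TRUE	core sigW	core
S742	-2.70	0.01	TRUE	C9	Yes	S742-yozO-S740-S739-yocM	1	.	TRUE	FALSE	core sigW	core
pspA	-2.68	0.01	TRUE	C6	Yes	pspA-ydjG-ydjH-ydjI	1	.	TRUE	TRUE	Secondary sigW	secondary
yfhL	-2.52	0.01	TRUE	C5	Yes	yfhL-yfhM	1	.	TRUE	TRUE	Secondary sigW	secondary
ydjG	-2.51	0.01	TRUE	C6	Yes	pspA-ydjG-ydjH-ydjI	2	.	TRUE	TRUE	Secondary sigW	secondary
S719	-2.49	0.01	TRUE	C9	Yes	yobJ-S719	2	.	TRUE	FALSE	core sigW	core
S658	-2.48	0.01	TRUE	C9	Yes	fosB-S658-S659	2	.	TRUE	FALSE	core sigW	core
ybfO	-2.47	0.01	TRUE	C9	Yes	ybfO-ybfP-S89	1	.	TRUE	TRUE	core sigW	core
ydbT	-2.47	0.01	TRUE	C6	Yes	ydbS-ydbT-S160-S161-acpS	2	.	TRUE	TRUE	Secondary sigW	secondary
ydbS	-2.46	0.01	TRUE	C6	Yes	ydbS-ydbT-S160-S161-acpS	1	.	TRUE	TRUE	Secondary sigW	secondary
pbpE	-2.33	0.01	TRUE	C9	Yes	pbpE-racX	1	.	TRUE	TRUE	core sigW	core
yuaG	-2.33	0.01	TRUE	C9	Yes	yuaF-yuaG-yuaI	2	.	TRUE	TRUE	core sigW	core
yfhM	-2.30	0.01	TRUE	C5	Yes	yfhL-yfhM	2	.	TRUE	TRUE	Secondary sigW	secondary
ydjH	-2.27	0.01	TRUE	C6	Yes	pspA-ydjG-ydjH-ydjI	3	.	TRUE	TRUE	Secondary sigW	secondary
yqfB	-2.25	0.01	FALSE	C9	Yes	yqeZ-yqfA-yqfB-yqfC-yqfD	3	.	TRUE	TRUE	core sigW	core
yobJ	-2.24	0.01	TRUE	C9	Yes	yobJ-S719	1	.	TRUE	TRUE	core sigW	core
yqeZ	-2.21	0.01	FALSE	C9	Yes	yqeZ-yqfA-yqfB-yqfC-yqfD	1	.	TRUE	TRUE	core sigW	core
ydjI	-2.17	0.01	TRUE	C6	Yes	pspA-ydjG-ydjH-ydjI	4	.	TRUE	TRUE	Secondary sigW	secondary
racX	-2.12	0.01	TRUE	C9	Yes	pbpE-racX	2	.	TRUE	TRUE	core sigW	core
yqfA	-2.11	0.01	FALSE	C9	Yes	yqeZ-yqfA-yqfB-yqfC-yqfD	2	.	TRUE	TRUE	core sigW	core
mtlF	-2.05	0.01	FALSE	C36	No	mtlA-mtlF-mtlD	2	.	FALSE	FALSE	background	background
yuaI	-2.02	0.01	TRUE	C9	Yes	yuaF-yuaG-yuaI	3	.	TRUE	TRUE	core sigW	core
mtlD	-1.97	0.01	FALSE	C36	No	mtlA-mtlF-mtlD	3	.	FALSE	FALSE	background	background
yvlA	-1.91	0.01	TRUE	C9	Yes	yvlA-yvlB-yvlC-yvlD-S1338	1	.	TRUE	TRUE	core sigW	core
yvlB	-1.85	0.01	TRUE	C9	Yes	yvlA-yvlB-yvlC-yvlD-S1338	2	.	TRUE	TRUE	core sigW	core
mtlA	-1.85	0.01	FALSE	C36	No	mtlA-mtlF-mtlD	1	.	FALSE	FALSE	background	background
ywrE	-1.82	0.01	FALSE	C9	Yes	ywrE-S1390	1	.	TRUE	TRUE	core sigW	core
yuaF	-1.78	0.01	TRUE	C9	Yes	yuaF-yuaG-yuaI	1	.	TRUE	TRUE	core sigW	core
yoaF	-1.58	0.01	FALSE	C48	Yes	yoaF	1	.	TRUE	TRUE	Secondary sigW	secondary
S160	-1.56	0.01	FALSE	C6	Yes	ydbS-ydbT-S160-S161-acpS	3	.	TRUE	FALSE	Secondary sigW	secondary
ybfP	-1.38	0.01	TRUE	C9	Yes	ybfO-ybfP-S89	2	.	TRUE	TRUE	core sigW	core
S89	-1.34	0.01	TRUE	C9	Yes	ybfO-ybfP-S89	3	.	TRUE	FALSE	core sigW	core
yvlD	-1.34	0.01	FALSE	C9	Yes	yvlA-yvlB-yvlC-yvlD-S1338	4	.	TRUE	TRUE	core sigW	core
yvlC	-1.32	0.01	FALSE	C9	Yes	yvlA-yvlB-yvlC-yvlD-S1338	3	.	TRUE	TRUE	core sigW	core
yjzH	-1.19	0.01	FALSE	C9	Yes	yjzH-S442	1	.	TRUE	FALSE	core sigW	core
sppA	-1.18	0.01	FALSE	C6	Yes	sppA-yteJ	1	.	TRUE	TRUE	Secondary sigW	secondary
yteJ	-1.17	0.01	TRUE	C6	Yes	sppA-yteJ	2	.	TRUE	TRUE	Secondary sigW	secondary
yaaN	-1.11	0.01	FALSE	C9	Yes	xpaC-yaaN-S22	2	.	TRUE	TRUE	core sigW	core
yceE	-1.04	0.01	FALSE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	4	.	TRUE	TRUE	Secondary sigW	secondary
S716	-0.95	0.01	FALSE	C31	Yes	S716	1	yobJ-S719	FALSE	FALSE	Read through	read_through
S659	-0.94	0.01	FALSE	C9	Yes	fosB-S658-S659	3	.	TRUE	FALSE	core sigW	core
yceD	-0.90	0.01	FALSE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	3	.	TRUE	TRUE	Secondary sigW	secondary
yceH	-0.88	0.01	TRUE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	7	.	TRUE	TRUE	Secondary sigW	secondary
S22	-0.88	0.01	FALSE	C9	Yes	xpaC-yaaN-S22	3	.	TRUE	FALSE	core sigW	core
yceG	-0.87	0.01	TRUE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	6	.	TRUE	TRUE	Secondary sigW	secondary
yceC	-0.84	0.01	FALSE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	2	.	TRUE	TRUE	Secondary sigW	secondary
yxjH	-0.83	0.01	FALSE	C48	Yes	yxjH	1	S1495-yxjJ-yxjI	FALSE	FALSE	Read through	read_through
ygzA	-0.82	0.01	FALSE	C2	No	ygzA	1	.	FALSE	FALSE	Background	background
S1338	-0.80	0.01	FALSE	C9	Yes	yvlA-yvlB-yvlC-yvlD-S1338	5	.	TRUE	FALSE	core sigW	core
ilvD	-0.78	0.01	FALSE	C48	No	ilvD	1	.	FALSE	FALSE	background	background
yknX	-0.78	0.01	FALSE	C9	Yes	yknW-yknX-yknY-yknZ	2	.	TRUE	TRUE	core sigW	core
S106	-0.78	0.01	FALSE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	1	.	TRUE	FALSE	Secondary sigW	secondary
xpaC	-0.77	0.01	FALSE	C9	Yes	xpaC-yaaN-S22	1	.	TRUE	TRUE	core sigW	core
yqfC	-0.76	0.01	TRUE	C2	Yes	yqeZ-yqfA-yqfB-yqfC-yqfD	4	.	TRUE	FALSE	Secondary sigW	secondary
yknY	-0.76	0.01	FALSE	C9	Yes	yknW-yknX-yknY-yknZ	3	.	TRUE	TRUE	core sigW	core
S1175	-0.75	0.01	FALSE	C1	No	S1175	1	.	FALSE	FALSE	background	background
yceF	-0.74	0.01	FALSE	C6	Yes	S106-yceC-yceD-yceE-yceF-yceG-yceH	5	.	TRUE	TRUE	Secondary sigW	secondary
yqfD	-0.72	0.01	TRUE	C2	Yes	yqeZ-yqfA-yqfB-yqfC-yqfD	5	.	TRUE	FALSE	Secondary sigW	secondary
yknZ	-0.69	0.01	FALSE	C9	Yes	yknW-yknX-yknY-yknZ	4	.	TRUE	TRUE	core sigW	core
mtnK	-0.65	0.01	FALSE	C48	No	mtnK-mtnA	1	.	FALSE	FALSE	background	background
alsD	-0.63	0.01	FALSE	C39	No	alsS-alsD	2	.	FALSE	FALSE	background	background
yozO	-0.60	0.01	FALSE	C9	Yes	S742-yozO-S740-S739-yocM	2	.	TRUE	TRUE	core sigW	core
yknW	-0.57	0.01	FALSE	C9	Yes	yknW-yknX-yknY-yknZ	1	.	TRUE	TRUE	core sigW	core
S740	-0.54	0.01	FALSE	C6	Yes	S742-yozO-S740-S739-yocM	3	.	TRUE	FALSE	Secondary sigW	secondary
S161	-0.52	0.01	FALSE	C3	Yes	ydbS-ydbT-S160-S161-acpS	4	.	TRUE	FALSE	Secondary sigW	secondary
S739	-0.51	0.01	FALSE	C2	Yes	S742-yozO-S740-S739-yocM	4	.	TRUE	FALSE	Secondary sigW	secondary
S1390	-0.48	0.01	FALSE	C9	Yes	ywrE-S1390	2	.	TRUE	FALSE	core sigW	core
S442	-0.48	0.01	FALSE	C9	Yes	yjzH-S442	2	.	TRUE	FALSE	core sigW	core
acpS	-0.45	0.01	FALSE	C3	Yes	ydbS-ydbT-S160-S161-acpS	5	.	TRUE	FALSE	Secondary sigW	secondary
S162	-0.44	0.01	FALSE	C2	Yes	S162-ydcC	1	.	TRUE	FALSE	Secondary sigW	secondary
ydcC	-0.42	0.01	FALSE	C2	Yes	S162-ydcC	2	.	TRUE	FALSE	Secondary sigW	secondary
thiC	-0.41	0.01	FALSE	C48	No	thiC	1	ygzA	FALSE	FALSE	Background	background
ydjO	-0.41	0.01	FALSE	C2	Yes	yeaA-ydjP-ydjO	3	.	TRUE	TRUE	Secondary sigW	secondary
yocM	-0.41	0.01	FALSE	C2	Yes	S742-yozO-S740-S739-yocM	5	.	TRUE	FALSE	Secondary sigW	secondary
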