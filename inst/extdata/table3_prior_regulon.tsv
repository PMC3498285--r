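feature	effect	p	cluster	motif	operon	operon_pos	salt_induced	prior_regulon	attributed_sigma	profile_label	other_sigma	conclusion_printed	call_expected
yxzE	-0.45	0.08	C9	Yes	yxzE-S1489	1	TRUE	TRUE	.	sigW-like	FALSE	core sigW	core
S1489	-0.31	0.50	C9	Yes	yxzE-S1489	2	TRUE	TRUE	.	sigW-like	FALSE	core sigW	core
bscR	-0.15	0.50	C10	Yes	yrhH-bscR-yrhJ	2	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
ywbO	-0.02	0.50	C29	No	ywbN-ywbO	2	FALSE	TRUE	Fur	unclassified	FALSE	Not sigW - Fur-regulated	not_regulated
fabHa	-0.03	0.50	C3	Yes	fabHA-fabF	1	FALSE	TRUE	.	unclassified	FALSE	sigW Kingston et al 2011	not_regulated
efeN	-0.04	0.50	C29	No	ywbL-ywbM-ywbN	3	FALSE	TRUE	Fur	unclassified	FALSE	Not sigW - Fur-regulated	not_regulated
fabF	-0.07	0.50	C3	Yes	fabHA-fabF	2	FALSE	TRUE	.	unclassified	FALSE	sigW Kingston et al 2011	not_regulated
yrhJ	-0.08	0.50	C10	Yes	yrhH-bscR-yrhJ	3	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
ywaC	0.06	0.50	C79	Yes	ywaC	1	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
yjbC	0.07	0.50	C5	Yes	yjbC-spx	1	FALSE	TRUE	sigB+sigM	sigM-like	TRUE	sigB and sigM	other_sigma
yjbD	0.17	0.50	C17	Yes	yjbC-spx	2	FALSE	TRUE	sigB+sigM	sigM-like	TRUE	sigB and sigM	other_sigma
divIC	0.23	0.50	C20	Yes	yabM-yabN-yabO-yabP-yabQ-divIC-yabR	6	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
yrhH	0.25	0.50	C10	Yes	yrhH-bscR-yrhJ	1	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
abh	0.30	0.50	C36	Yes	abh	1	FALSE	TRUE	sigX	unclassified	TRUE	sigX	other_sigma
ywnJ	0.31	0.50	C2	Yes	ywnJ	1	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
bcrC	0.33	0.50	C10	Yes	bcrC	1	FALSE	TRUE	sigM	sigM-like	TRUE	sigM	other_sigma
yqjL	0.37	0.50	C78	Yes	yqjL	1	FALSE	TRUE	sigB+sigM	sigM-like	TRUE	sigB, sigM	other_sigma
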