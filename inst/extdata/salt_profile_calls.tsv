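feature	profile_label	salt_induced	previously_reported
rsiW	sigW-like	TRUE	TRUE
sigW	sigW-like	TRUE	TRUE
spo0M	sigW-like	TRUE	TRUE
S691	sigW-like	TRUE	FALSE
yeaA	sigW-like	TRUE	TRUE
ysdB	sigW-like	TRUE	TRUE
yjoB	sigW-like	TRUE	TRUE
ydjP	sigW-like	TRUE	TRUE
S462	sigW-like	TRUE	FALSE
yxjI	sigW-like	TRUE	TRUE
yoaG	sigW-like	TRUE	TRUE
fosB	sigW-like	TRUE	TRUE
ythP	sigW-like	TRUE	TRUE
S690	sigW-like	TRUE	FALSE
S1495	sigW-like	TRUE	FALSE
ythQ	sigW-like	TRUE	TRUE
S742	sigW-like	TRUE	FALSE
pspA	sigW-like	TRUE	TRUE
yfhL	sigW-like	TRUE	TRUE
ydjG	sigW-like	TRUE	TRUE
S719	sigW-like	TRUE	FALSE
S658	sigW-like	TRUE	FALSE
ybfO	sigW-like	TRUE	TRUE
ydbT	sigW-like	TRUE	TRUE
ydbS	sigW-like	TRUE	TRUE
pbpE	sigW-like	TRUE	TRUE
yuaG	sigW-like	TRUE	TRUE
yfhM	sigW-like	TRUE	TRUE
ydjH	sigW-like	TRUE	TRUE
yqfB	sigW-like	TRUE	TRUE
yobJ	sigW-like	TRUE	TRUE
yqeZ	sigW-like	TRUE	TRUE
ydjI	sigW-like	TRUE	TRUE
racX	sigW-like	TRUE	TRUE
yqfA	sigW-like	TRUE	TRUE
yuaI	sigW-like	TRUE	TRUE
yvlA	sigW-like	TRUE	TRUE
yvlB	sigW-like	TRUE	TRUE
ywrE	sigW-like	TRUE	TRUE
yuaF	sigW-like	TRUE	TRUE
yoaF	sigW-like	TRUE	TRUE
S160	sigW-like	TRUE	FALSE
ybfP	sigW-like	TRUE	TRUE
S89	sigW-like	TRUE	FALSE
yvlD	sigW-like	TRUE	TRUE
yvlC	sigW-like	TRUE	TRUE
yjzH	sigW-like	TRUE	FALSE
sppA	sigW-like	TRUE	TRUE
yteJ	sigW-like	TRUE	TRUE
yaaN	sigW-like	TRUE	TRUE
yceE	sigW-like	TRUE	TRUE
S659	sigW-like	TRUE	FALSE
yceD	sigW-like	TRUE	TRUE
yceH	sigW-like	TRUE	TRUE
S22	sigW-like	TRUE	FALSE
yceG	sigW-like	TRUE	TRUE
yceC	sigW-like	TRUE	TRUE
S1338	sigW-like	TRUE	FALSE
yknX	sigW-like	TRUE	TRUE
S106	sigW-like	TRUE	FALSE
xpaC	sigW-like	TRUE	TRUE
yqfC	sigW-like	TRUE	FALSE
yknY	sigW-like	TRUE	TRUE
yceF	sigW-like	TRUE	TRUE
yqfD	sigW-like	TRUE	FALSE
yknZ	sigW-like	TRUE	TRUE
yozO	sigW-like	TRUE	TRUE
yknW	sigW-like	TRUE	TRUE
S740	sigW-like	TRUE	FALSE
S161	sigW-like	TRUE	FALSE
S739	sigW-like	TRUE	FALSE
S1390	sigW-like	TRUE	FALSE
S442	sigW-like	TRUE	FALSE
acpS	sigW-like	TRUE	FALSE
S162	sigW-like	TRUE	FALSE
ydcC	sigW-like	TRUE	FALSE
ydjO	sigW-like	TRUE	TRUE
yocM	sigW-like	TRUE	FALSE
yxzE	sigW-like	TRUE	TRUE
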