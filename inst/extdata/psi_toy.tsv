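event_id	event_type	isoform_id	fraction	psi	ci_low	ci_high
ev1	AFE	ev1.1	3	0.1	0.05	0.15
ev1	AFE	ev1.1	4	0.3	0.25	0.35
ev1	AFE	ev1.1	5	0.9	0.85	0.95
ev1	AFE	ev1.2	3	0.9	0.85	0.95
ev1	AFE	ev1.2	4	0.7	0.65	0.75
ev1	AFE	ev1.2	5	0.1	0.05	0.15
ev2	ALE	ev2.1	3	0.5	0.475	0.525
ev2	ALE	ev2.1	4	0.6	0.575	0.625
ev2	ALE	ev2.1	5	0.8	0.775	0.825
ev2	ALE	ev2.2	3	0.5	0.475	0.525
ev2	ALE	ev2.2	4	0.4	0.375	0.425
ev2	ALE	ev2.2	5	0.2	0.175	0.225
ev3	AFE	ev3.1	3	0.45	0.4	0.5
ev3	AFE	ev3.1	4	0.5	0.45	0.55
ev3	AFE	ev3.1	5	0.55	0.5	0.6
ev3	AFE	ev3.2	3	0.55	0.5	0.6
ev3	AFE	ev3.2	4	0.5	0.45	0.55
ev3	AFE	ev3.2	5	0.45	0.4	0.5
ev4	ALE	ev4.1	3	0.2	0.15	0.25
ev4	ALE	ev4.1	4	0.5	0.375	0.625
ev4	ALE	ev4.1	5	0.7	0.65	0.75
ev4	ALE	ev4.2	3	0.8	0.75	0.85
ev4	ALE	ev4.2	4	0.5	0.45	0.55
ev4	ALE	ev4.2	5	0.3	0.25	0.35
ev5	AFE	ev5.1	3	0.4	0.325	0.475
ev5	AFE	ev5.1	4	0.4	0.325	0.475
ev5	AFE	ev5.1	5	0.4	0.325	0.475
ev5	AFE	ev5.2	3	0.6	0.525	0.675
ev5	AFE	ev5.2	4	0.6	0.525	0.675
ev5	AFE	ev5.2	5	0.6	0.525	0.675
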