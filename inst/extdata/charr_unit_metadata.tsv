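population	lake	ecotype	latitude	longitude	ecotype_esu	sole_ha	translocation_group	shared_history_group	unit_type
a'Bhaid-Luachraich	a'Bhaid-Luachraich	unimodal	57.81	-5.55	FALSE	FALSE			MU
a'Garbh-bhaid Mor	a'Garbh-bhaid Mor	unimodal	58.39	-4.95	FALSE	FALSE			MU
Ard Achadh	Ard Achadh	unimodal	55.36	-6.16	FALSE	FALSE			MU
Arkaig (Benthivore)	Arkaig	benthivore	56.97	-5.14	TRUE	FALSE			ESU
Arkaig (Planktivore)	Arkaig	planktivore	56.97	-5.14	TRUE	FALSE			ESU
Awe (Benthivore)	Awe	benthivore	56.30	-5.23	TRUE	FALSE			ESU
Awe (Planktivore)	Awe	planktivore	56.30	-5.23	TRUE	FALSE			ESU
Braig horrisdale	Braig horrisdale	unimodal	57.67	-5.67	FALSE	FALSE			MU
Brora	Brora	unimodal	58.05	-3.95	FALSE	FALSE			MU
Bruicheach	Bruicheach	unimodal	57.39	-4.58	FALSE	TRUE			ESU
Calder	Calder	unimodal	58.52	-3.59	FALSE	FALSE			MU
Coulin	Coulin	unimodal	57.55	-5.35	FALSE	FALSE		SH1	ESU
Damh	Damh	unimodal	57.50	-5.57	FALSE	FALSE			MU
Doine	Doine	unimodal	56.34	-4.48	TRUE	FALSE			ESU
Doon	Doon	unimodal	55.24	-4.37	FALSE	TRUE	T1		ESU
Dubh	Dubh	unimodal	56.88	-5.71	FALSE	FALSE			MU
Dughaill (Benthivore)	Dughaill	benthivore	57.47	-5.35	TRUE	FALSE			ESU
Dughaill (Planktivore)	Dughaill	planktivore	57.47	-5.35	TRUE	FALSE		SH1	ESU
Duntelchaig	Duntelchaig	unimodal	57.35	-4.29	FALSE	FALSE			MU
Earn	Earn	unimodal	56.38	-4.23	FALSE	TRUE			ESU
Eck	Eck	unimodal	56.08	-4.99	FALSE	TRUE			ESU
Ericht (Benthivore)	Ericht	benthivore	56.82	-4.39	TRUE	FALSE			ESU
Ericht (Planktivore)	Ericht	planktivore	56.82	-4.39	TRUE	FALSE		SH2	ESU
Fannich	Fannich	unimodal	57.64	-4.96	FALSE	FALSE		SH1	ESU
Garry	Garry	unimodal	56.80	-4.25	FALSE	FALSE		SH2	ESU
Insh	Insh	unimodal	57.12	-3.93	FALSE	FALSE			MU
Laggan	Laggan	unimodal	56.92	-4.55	FALSE	FALSE		SH3	MU
Langavat	Langavat	unimodal	58.04	-6.82	FALSE	FALSE			MU
Lee	Lee	unimodal	56.90	-2.95	FALSE	TRUE			ESU
Loch	Loch	unimodal	56.85	-3.67	FALSE	FALSE			MU
Lochy (Benthivore)	Lochy	benthivore	56.96	-4.92	TRUE	FALSE			ESU
Lochy (Planktivore)	Lochy	planktivore	56.96	-4.92	TRUE	FALSE			ESU
Lubnaig	Lubnaig	unimodal	56.30	-4.30	TRUE	FALSE			ESU
Luichart	Luichart	unimodal	57.62	-4.78	FALSE	FALSE			MU
Maree	Maree	unimodal	57.71	-5.53	TRUE	FALSE			ESU
Meadie	Meadie	unimodal	58.33	-4.56	FALSE	FALSE			MU
Mealt	Mealt	unimodal	57.61	-6.18	FALSE	FALSE			MU
Merkland	Merkland	unimodal	58.23	-4.73	TRUE	FALSE			ESU
More	More	unimodal	58.28	-4.87	TRUE	FALSE			ESU
Morie	Morie	unimodal	57.75	-4.47	FALSE	FALSE			MU
Nam Brac	Nam Brac	unimodal	58.38	-5.12	FALSE	FALSE			MU
naSealga (Benthivore)	naSealga	benthivore	57.79	-5.31	TRUE	FALSE			ESU
naSealga (Planktivore)	naSealga	planktivore	57.79	-5.31	TRUE	FALSE			ESU
Naver	Naver	unimodal	58.30	-4.35	FALSE	FALSE			MU
Osgaig	Osgaig	unimodal	58.05	-5.32	FALSE	FALSE			MU
Rannoch (Benthivore)	Rannoch	benthivore	56.70	-4.23	TRUE	FALSE			ESU
Rannoch (Planktivore)	Rannoch	planktivore	56.70	-4.23	TRUE	FALSE			ESU
Rannoch (Piscivore)	Rannoch	piscivore	56.70	-4.23	TRUE	FALSE			ESU
Seil	Seil	unimodal	56.32	-5.55	FALSE	FALSE			MU
Shin	Shin	unimodal	58.12	-4.57	TRUE	FALSE			ESU
Stack	Stack	unimodal	58.34	-4.92	TRUE	FALSE			ESU
Talla	Talla	unimodal	55.48	-3.40	FALSE	FALSE	T1		ESU
Tarff	Tarff	unimodal	57.15	-4.61	FALSE	FALSE			MU
Tay (Benthivore)	Tay	benthivore	56.52	-4.14	TRUE	FALSE			ESU
Tay (Planktivore)	Tay	planktivore	56.52	-4.14	TRUE	FALSE			ESU
Treig	Treig	unimodal	56.81	-4.73	FALSE	FALSE		SH3	MU
Tummel	Tummel	unimodal	56.71	-3.95	FALSE	FALSE			MU
Uaine	Uaine	unimodal	57.52	-5.39	FALSE	FALSE		SH1	ESU
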