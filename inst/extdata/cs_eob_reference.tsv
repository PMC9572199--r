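isomer	md_rank	dock_rank	eob	sd	sites	strongest
CS6	1	2	-2522	339	IA-IB-IIA-IIIA-IIIB	IIIA
CS6	2	6	-2133	301	IB-IIIA-IIIB	IIIB
CS6	3	9	-1694	665	IB-IIIA-IIIB	IIIB
CS6	4	7	-1670	388	IA-IIA-IIB-IIIA	IA
CS6	5	1	-1628	792	IA-IIA-IIIA-IIIB	IIIB
CS6	6	5	-1542	665	IA-IIA-IIIA-IIIB	IIIB
CS6	7	4	-1498	399	IA-IIA-IIIA-IIIB	IIIB
CS6	8	3	-1472	675	IA-IIA	IIA
CS6	9	10	-1363	550	IIA-IIB	IIB
CS6	10	8	-1033	453	IA-IB	IA
CS4	1	3	-2755	624	IB-IIIA-IIIB	IIIB
CS4	2	9	-2737	386	IB-IIA-IIIA-IIIB	IIIA
CS4	3	8	-2194	702	IA-IB-IIA	IIA
CS4	4	10	-1906	556	IA-IB-IIA-IIIA	IA
CS4	5	4	-1904	441	IA-IB-IIA-IIB	IIA
CS4	6	5	-1641	659	IB-IIA-IIB-IIIA-IIIB	IIIA
CS4	7	7	-1639	374	IA-IB-IIA-IIIA-IIIB	IA
CS4	8	2	-1637	674	IA-IB-IIIA-IIIB	IB
CS4	9	1	-1613	531	IB-IIA-IIIA-IIIB	IIIB
CS4	10	6	-1516	493	IB-IIIA-IIIB	IIIB
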