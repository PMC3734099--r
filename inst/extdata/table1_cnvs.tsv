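locus_entry	locus	chrom	genes	furthest_distance	bin	sample_id	cnv_type	start	end	size
1	2p16.3	2	NRXN1	1124	ii	1-0045-004	loss	51405882	51524684	118802
1	2p16.3	2	NRXN1	1124	ii	8-3394-003	loss	51439897	51479683	39786
1	2p16.3	2	NRXN1	1124	ii	8-3394-003	loss	51157414	51189362	31948
1	2p16.3	2	NRXN1	1124	ii	8-14144-2420	loss	51157414	51225851	68437
1	2p16.3	2	NRXN1	1124	ii	1-0496-003	gain	52220120	52238172	18052
1	2p16.3	2	NRXN1	1124	ii	1-0449-003	loss	52237072	52253660	16588
2	3p22.3	3	ARPP21	563	ii	2-1213-003	loss	34984049	35102773	118724
2	3p22.3	3	ARPP21	563	ii	3-0100-000	gain	35086691	35094736	8045
3	3q24	3	C3orf58;ZIC1;ZIC4	1383;1955;1979	i	1-0007-003	loss	146168760	146934953	766193
3	3q24	3	C3orf58;ZIC1;ZIC4	1383;1955;1979	i	8-3093-004	loss	146575437	146631141	55704
4	4q13.1	4	EPHA5	840	i	8-14208-3350	loss	66505324	66633530	128206
4	4q13.1	4	EPHA5	840	i	8-14186-3050	loss	66515708	66633530	117822
4	4q13.1	4	EPHA5	840	i	1-0138-004	loss	66515708	66633530	117822
4	4q13.1	4	EPHA5	840	i	2-0082-004	loss	67045815	67134170	88355
4	4q13.1	4	EPHA5	840	i	1-0455-003	loss	67058506	67075558	17052
5	6p21.2	6	MOCS1	168	i or ii	3-0139-000	gain	40021898	40078515	56617
5	6p21.2	6	MOCS1	168	i or ii	2-0139-003	gain	40023327	40062155	38828
5	6p21.2	6	MOCS1	168	i or ii	1-0381-003	loss	40174188	40209324	35136
5	6p21.2	6	MOCS1	168	i or ii	2-1368-003	loss	40174188	40210694	36506
6	7q21.11	7	SEMA3C	96	i	8-6258-03	loss	80431202	80512022	80820
6	7q21.11	7	SEMA3C	96	i	1-0345-005	loss	80482597	80517630	35033
7	8p12	8	UNC5D;NRG1	256;2183	i	8-14243-3670	loss	34923482	34956067	32585
7	8p12	8	UNC5D;NRG1	256;2183	i	3-0044-000	loss	34923482	34956067	32585
7	8p12	8	UNC5D;NRG1	256;2183	i	3-0300-000	loss	34925149	34957854	32705
7	8p12	8	UNC5D;NRG1	256;2183	i	8-14181-2940	loss	34923482	34956067	32585
8	8q24.13	8	ZHX2	237	i or ii	8-3317-003	gain	123572785	123625681	52896
8	8q24.13	8	ZHX2	237	i or ii	3-0186-000	loss	123583028	123639417	56389
9	9q33.1	9	ASTN2	98	i	8-3055-004	loss	119254497	119374796	120299
9	9q33.1	9	ASTN2	98	i	3-0115-000	loss	119314967	119319559	4592
10	9q34.2	9	OLFM1;RXRA	508;8	i	2-1272-003	gain	136479329	136604233	124904
10	9q34.2	9	OLFM1;RXRA	508;8	i	2-1189-003	gain	136480334	136598491	118157
11	11p14.3	11	LUZP2	160	i or ii	8-14175-2820	loss	24177612	24316053	138441
11	11p14.3	11	LUZP2	160	i or ii	8-14059-1020	loss	24262511	24303132	40621
11	11p14.3	11	LUZP2	160	i or ii	8-14208-3350	loss	24262511	24303132	40621
12	11p12	11	LRRC4C	196	iii	8-14208-3350	gain	40304880	40703298	398418
12	11p12	11	LRRC4C	196	iii	2-0272-003	loss	40379668	40550356	170688
12	11p12	11	LRRC4C	196	iii	SK0167-003	loss	40417554	40610400	192846
12	11p12	11	LRRC4C	196	iii	3-0208-000	loss	40468058	40492541	24483
13	11p12	11	LRRC4C	1738	i or ii	8-14032-600	loss	41990280	42021250	30970
13	11p12	11	LRRC4C	1738	i or ii	8-3276-003	loss	42243624	42279094	35470
13	11p12	11	LRRC4C	1738	i or ii	2-0286-003	loss	42243624	42279094	35470
14	11q13.2	11	MRGPRD	10	i	4-0023-003	loss	68486121	68493638	7517
14	11q13.2	11	MRGPRD	10	i	2-1075-003	loss	68486121	68500238	14117
15	16q21	16	CDH8	1030	i or ii	8-14251-3750	loss	61650435	61787984	137549
15	16q21	16	CDH8	1030	i or ii	2-1175-003	loss	61658675	61755232	96557
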