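block	region	enhancer_id	meth_direction	target_gene	expr_direction	p
Promoter	chr12:108733790-108734067	GH12J108336	Hyper	CMKLR1	Down	0.0108
Promoter/enhancer	chr2:222312663-222313620	GH02J221447	Hyper	EPHA4	Up	0.0130
Promoter/enhancer	chr2:74375246-74375595	GH02J074146	Hyper	AUP1	Down	0.0433
Promoter/enhancer	chr12:108733790-108734067	GH12J108336	Hyper	CMKLR1	Down	0.0108
Promoter/enhancer	chr12:48289327-48289770	GH12J047896	Hyper	DDX23	Down	0.0122
Promoter/enhancer	chr11:126030937-126031289	GH11J126157	Hyper	FAM118B	Down	0.0181
Promoter/enhancer	chr2:74375246-74375595	GH02J074146	Hyper	HTRA2	Down	0.0433
Promoter/enhancer	chr22:22128415-22128928	GH22J021772	Hyper	IGLV5-52	Down	0.0424
Promoter/enhancer	chr19:30158120-30158513	GH19J029660	Hyper	PLEKHF1	Down	0.0241
Promoter/enhancer	chr11:116699588-116699946	GH11J116825	Hyper	SIDT2	Down	0.0159
Promoter/enhancer	chr1:161513847-161514197	GH01J161539	Hyper	SLAMF7	Down	0.0324
Promoter/enhancer	chr11:116699588-116699946	GH11J116825	Hyper	TAGLN	Down	0.0116
Promoter/enhancer	chr1:92291397-92291719	GH01J091825	Hyper	TGFBR3	Down	0.0376
Promoter/enhancer	chr5:372991-373651	GH05J000367	Hypo	AHRR	Up	0.0324
Promoter/enhancer	chr3:98239609-98240661	GH03J098521	Hypo	CLDND1	Up	0.0220
Promoter/enhancer	chr3:169757128-169757597	GH03J170037	Hypo	GPR160	Up	0.0131
Promoter/enhancer	chr19:19928614-19928997	GH19J019816	Hypo	ZNF506	Up	0.0348
Promoter/enhancer	chr19:38186831-38187042	GH19J037695	Hypo	ZNF793	Up	0.0194
Promoter/enhancer	chr17:73684198-73684529	GH17J075683	Hypo	LLGL2	Down	0.0316
Promoter/enhancer	chr11:67024748-67025170	GH11J067257	Hypo	RAD9A	Down	0.0420
Promoter/enhancer	chr9:116164296-116164796	GH09J113396	Hypo	RGS3	Down	0.0001
Promoter/enhancer	chr22:46442102-46442610	GH22J046040	Hypo	TTC38	Down	0.0179
Promoter/enhancer	chr7:148723197-148723699	GH07J149026	Hypo	ZNF282	Down	0.0220
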