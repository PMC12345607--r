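genus	treatment_fraction	replicate_fraction	total_count
Deinococcus	0.9954	0.9948	11419
Sphingobium	0.9821	0.9821	1061
Luteibacter	0.9632	0.9628	15257
Citrobacter	0.9438	0.9424	5430
Xanthomonas	0.9410	0.9384	2304
Paraburkholderia	0.9274	0.9274	124
Rhodanobacter	0.9200	0.9189	109638
Klebsiella	0.9099	0.9080	1631
Humibacter	0.8922	0.8660	306
Enterobacter	0.8906	0.8890	43554
Herbaspirillum	0.8754	0.8754	666
Bacillus	0.8488	0.8476	10288
Phenylobacterium	0.8403	0.8403	238
Serratia	0.8286	0.8286	426
Dyella	0.8266	0.8252	738
Acinetobacter	0.7849	0.7849	172
Kosakonia	0.7448	0.7448	968
Telluria	0.7326	0.7209	86
Devosia	0.7320	0.7295	403
Pseudolabrys	0.7273	0.6591	88
Escherichia	0.6821	0.6807	10034
Novosphingobium	0.6517	0.5493	2159
Leifsonia	0.6376	0.5486	2111
Acidovorax	0.6295	0.6235	672
Brevundimonas	0.6074	0.6070	11276
Paenibacillus	0.6010	0.5984	381
Chryseobacterium	0.5509	0.5503	22244
Stenotrophomonas	0.5471	0.5471	4005
Bordetella	0.5463	0.5458	2248
Caulobacter	0.5315	0.5280	286
Ramlibacter	0.5312	0.5312	160
Asticcacaulis	0.5312	0.5312	1299
Lysinimonas	0.5280	0.4800	125
Pedobacter	0.4979	0.4976	21383
Erwinia	0.4918	0.4895	1287
Achromobacter	0.4688	0.4688	689
Thermomonas	0.4613	0.4611	4875
Ulvibacter	0.4609	0.4609	256
Unclassified	0.4374	0.4109	47141
Janthinobacterium	0.4258	0.4254	4403
Lysobacter	0.4164	0.4164	305
Hydrogenophaga	0.4016	0.4016	381
Pantoea	0.3995	0.3939	21089
Sphingomonas	0.3905	0.3342	1493
Staphylococcus	0.3857	0.3831	770
Mesorhizobium	0.3787	0.3577	478
Saccharopolyspora	0.3738	0.3641	206
Curtobacterium	0.3658	0.3658	2258
Cutibacterium	0.3593	0.3593	462
Ktedonobacter	0.3561	0.3485	132
Rhizobium	0.3549	0.3502	4477
Luteimonas	0.3485	0.3485	264
Peredibacter	0.3299	0.3260	776
Sinorhizobium	0.3153	0.3114	517
Flavobacterium	0.3146	0.3128	5467
Shinella	0.3110	0.3106	4994
Propionibacterium	0.3090	0.3057	3278
Burkholderia	0.3018	0.2966	4798
Arachidicoccus	0.2986	0.2986	278
Arthrobacter	0.2880	0.2139	10824
Bradyrhizobium	0.2796	0.1935	93
Methylobacillus	0.2704	0.1415	318
Variovorax	0.2693	0.2550	2310
Pseudacidovorax	0.2664	0.2617	214
Paracoccus	0.2652	0.1973	2017
Pseudomonas	0.2609	0.2126	468875
Massilia	0.2554	0.2551	56338
Mycobacterium	0.2500	0.1304	92
Pelomonas	0.2365	0.2365	148
Pandoraea	0.2102	0.2096	1889
Solimonas	0.2032	0.2032	1604
Microbacterium	0.1998	0.1864	4334
Nocardioides	0.1953	0.1523	256
Paenarthrobacter	0.1915	0.1785	2992
Methylophilus	0.1795	0.1776	4876
Liberibacter	0.1696	0.1627	2299
Caenibaculum	0.1229	0.1208	480
Buchnera	0.0098	0.0033	92054787
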