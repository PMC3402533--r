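name	genus	named_species	n_pilot	n_main	major_mode	major_lo	major_hi	minor_modes	minor_lo	minor_hi	linked_wobble	link_interval_bp	acid_mode	h2o2_mode	double_strong_n	gram	percent_identity_mode
L. sp. N6	Lactobacillus	FALSE	12	96	290	289	290	488	487	491	FALSE	NA	0	1	2	gpr	90
L. sp. N27	Lactobacillus	FALSE	7	17	283	283	283	479	479	480	FALSE	NA	2	0-1	0	gpr	90
L. oris	Lactobacillus	TRUE	1	0	291	291	291	183	183	183	FALSE	NA	2	2	0	gpr	99
L. sp. N19	Lactobacillus	FALSE	2	0	290	290	290	485	485	485	FALSE	NA	2	2	0	gpr	90
L. reuteri	Lactobacillus	TRUE	2	9	289	289	289	491	491	491	FALSE	NA	1	2	1	gpr	99
L. coleohominis	Lactobacillus	TRUE	0	30	284	284	284	488	488	489	FALSE	NA	0	1	0	gpr	99
P. pentosaceus	Pediococcus	TRUE	0	3	315	315	315	505	505	505	FALSE	NA	3	2	3	gpc	99
W. cibaria	Weissella	TRUE	0	1	337	337	337	356	356	356	FALSE	NA	2	2	0	gpc	99
L. plantarum	Lactobacillus	TRUE	0	1	291	291	291	521	521	521	FALSE	NA	3	1	0	gpr	99
L. ruminis	Lactobacillus	TRUE	0	6	300	299	300	400	400	401	FALSE	NA	3	2	3	gpr	99
L. animalis	Lactobacillus	TRUE	0	24	288	288	289	386	386	386	FALSE	NA	3	0	5	gpr	99
L. salivarius	Lactobacillus	TRUE	4	26	293	293	293	509	509	510	FALSE	NA	3	1	10	gpr	99
L. delbrueckii	Lactobacillus	TRUE	0	3	304	304	304	545	545	545	FALSE	NA	3	3	2	gpr	99
L. gasseri	Lactobacillus	TRUE	32	27	308	306	308	538	538	539	FALSE	NA	1	1	1	gpr	99
L. jensenii	Lactobacillus	TRUE	30	32	288	288	288	525	525	526	FALSE	NA	1	1	0	gpr	99
L. crispatus	Lactobacillus	TRUE	61	47	293	293	294	546	546	547	FALSE	NA	0	1	0	gpr	99
E. faecalis	Enterococcus	TRUE	1	7	313	313	313	415	414	415	FALSE	NA	2	1	0	gpc	99
E. raffinosus	Enterococcus	TRUE	0	2	311	311	311	413	413	413	FALSE	NA	2	3	2	gpc	99
S. bovis	Streptococcus	TRUE	0	17	361	361	361				FALSE	NA	2	2	4	gpc	99
S. lutetiensis	Streptococcus	TRUE	6	14	360	360	360				FALSE	NA	1	0	1	gpc	99
S. agalactiae	Streptococcus	TRUE	0	31	368	367	368				FALSE	NA	2	2	0	gpc	99
S. sp. N80	Streptococcus	FALSE	0	16	331	331	331				FALSE	NA	1	1	0	gpc	90
S. sp. N127	Streptococcus	FALSE	1	10	335	334	336				FALSE	NA	1	1	0	gpc	90
S. anginosus	Streptococcus	TRUE	0	5	477	477	479				FALSE	NA	2	2	0	gpc	99
S. constellatus	Streptococcus	TRUE	7	25	383	382	383				FALSE	NA	2	2	0	gpc	99
Pe. harei	Peptoniphilus	TRUE	0	1	470	470	470				FALSE	NA	1	1	0	gpc	99
B. cereus	Bacillus	TRUE	0	1	230	230	230	459	459	459	FALSE	NA	1	1	0	gpr	99
Ge. haemolysans	Gemella	TRUE	0	2	298	298	301	504	504	508	TRUE	-206	1	2	0	gpc	99
St. simulans	Staphylococcus	TRUE	0	1	333	333	333	424	424	424	FALSE	NA	0	1	0	gpc	99
St. haemolyticus	Staphylococcus	TRUE	0	2	425	425	425				FALSE	NA	1	0	0	gpc	99
St. hominis	Staphylococcus	TRUE	0	1	388	388	388				FALSE	NA	1	0	0	gpc	99
St. epidermidis	Staphylococcus	TRUE	4	8	350	350	353	444	444	446	FALSE	NA	1	0	0	gpc	99
St. lugdunensis	Staphylococcus	TRUE	0	3	351	351	351				FALSE	NA	1	0	0	gpc	99
St. piscifermentans	Staphylococcus	TRUE	0	1	NA	NA	NA				FALSE	NA	2	0	0	gpc	99
Pr. bivia	Prevotella	TRUE	0	2	537	537	543	771	771	774	FALSE	NA	1	0	0	gnr	99
Pr. disiens	Prevotella	TRUE	0	1	583	583	583	354	354	354	FALSE	NA	1	0	0	gnr	99
Ba. fragilis	Bacteroides	TRUE	0	2	570	570	575				FALSE	NA	1	0	0	gnr	99
E. coli	Escherichia	TRUE	0	5	439	439	439	429	429	429	FALSE	NA	1	0	0	gnr	99
K. pneumoniae	Klebsiella	TRUE	0	1	291	291	291	435	435	435	FALSE	NA	1	0	0	gnr	99
N159	unassigned	FALSE	0	1	397	397	397				FALSE	NA	1	0	0	unknown	90
Bi. longum	Bifidobacterium	TRUE	6	8	177	177	182				FALSE	NA	2	0	0	gpr	99
Bi. catenulatum	Bifidobacterium	TRUE	0	9	530	527	532	227	227	227	FALSE	NA	3	0	4	gpr	99
G. vaginalis	Gardnerella	TRUE	5	63	459	438	466	441	438	460	TRUE	15	0	0	1	gvcb	99
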