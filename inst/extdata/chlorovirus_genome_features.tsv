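genome_id	host_group	n_contigs	genome_size_kb	coverage	gc	n_protein_genes	n_trna_genes	n_protein_families	accession
AN69C	NC64A	8	332	29	40	362	10	278	JX997153
CviKI	NC64A	8	308	55	40	336	14	271	JX997162
CvsA1	NC64A	9	310	36	40	342	14	272	JX997165
IL-3A	NC64A	3	323	50	40	349	12	273	JX997169
IL-5-2s1	NC64A	9	344	65	41	379	8	281	JX997170
KS1B	NC64A	7	287	46	40	319	13	257	JX997171
MA-1D	NC64A	9	339	45	41	371	11	288	JX997172
MA-1E	NC64A	39	336	27	40	376	14	269	JX997173
NE-JV-4	NC64A	8	328	41	40	352	11	276	JX997179
NY-2B	NC64A	5	344	59	41	371	8	281	JX997182
NYs-1	NC64A	9	348	64	41	381	7	286	JX997183
AP110A	Pbi	6	327	27	44	348	9	269	JX997154
Can18-4	Pbi	11	329	52	45	357	10	271	JX997157
CVA-1	Pbi	8	326	36	45	346	9	270	JX997159
CVB-1	Pbi	8	319	90	44	346	10	272	JX997160
CVG-1	Pbi	7	318	48	45	333	9	262	JX997161
CVM-1	Pbi	5	327	48	44	341	9	268	JX997163
CVR-1	Pbi	11	329	39	45	351	9	268	JX997164
CZ-2	Pbi	11	305	39	45	340	10	262	JX997166
Fr5L	Pbi	22	302	58	45	345	11	257	JX997167
NE-JV-1	Pbi	8	326	45	47	337	3	265	JX997176
NW665.2	Pbi	6	325	62	44	350	8	263	JX997181
OR0704.2.2	Pbi	8	313	53	45	344	7	261	JX997184
Br0604L	SAG	2	295	65	49	346	9	272	JX997155
Can0610SP	SAG	1	307	61	49	341	13	267	JX997156
Canal-1	SAG	4	293	50	51	336	10	277	JX997158
GM0701.1	SAG	4	315	71	48	362	10	272	JX997168
MN0810.1	SAG	6	327	57	52	343	9	268	JX997174
MO0605SPH	SAG	3	289	107	49	323	11	271	JX997175
NE-JV-2	SAG	4	319	40	48	346	13	271	JX997177
NE-JV-3	SAG	3	298	63	49	334	12	268	JX997178
NTS-1	SAG	4	323	35	48	364	7	271	JX997180
OR0704.3	SAG	5	311	49	49	342	13	272	JX997185
TN603.4.2	SAG	3	321	28	49	351	9	276	JX997186
WI0606	SAG	7	289	58	50	329	11	271	JX997187
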